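#' VanRaden genomic relationship matrix
#'
#' Dosages are centered by twice the allele frequency and
#' `K = M M' / (2 * sum(p (1 - p)))`. Monomorphic markers are excluded
#' with a count.
#'
#' @param panel complete [genotype_panel()].
#' @return symmetric n x n matrix with the centering frequencies in
#'   `attr(, "p_hat")`.
#' @export
kinship_vanraden <- function(panel) {
  p <- colMeans(panel$dosage) / 2
  mono <- p == 0 | p == 1
  if (any(mono)) message("kinship: excluded ", sum(mono), " monomorphic markers")
  X <- panel$dosage[, !mono, drop = FALSE]
  p <- p[!mono]
  Mc <- sweep(X, 2, 2 * p)
  K <- tcrossprod(Mc) / (2 * sum(p * (1 - p)))
  attr(K, "p_hat") <- p
  K
}

reml_delta <- function(yr, Xr, S, log_range = c(-10, 10), tol = 1e-6) {
  n <- length(yr); p <- ncol(Xr)
  obj <- function(ld) {
    d <- exp(ld)
    w <- 1 / (S + d)
    sw <- sqrt(w)
    Xw <- Xr * sw; yw <- yr * sw
    qrX <- qr(Xw)
    rss <- sum(qr.resid(qrX, yw)^2)
    Rd <- abs(diag(qr.R(qrX)))
    (n - p) * log(rss) + sum(log(S + d)) + 2 * sum(log(Rd))
  }
  opt <- stats::optimize(obj, interval = log_range, tol = tol)
  exp(opt$minimum)
}

#' Multi-locus mixed-model GWAS scan
#'
#' Stepwise mixed-model regression under a polygenic kinship background:
#' `y = X b + u + e`, `u ~ N(0, K sigma2_g)`. The variance ratio
#' `delta = sigma2_e / sigma2_g` is re-estimated once per step by REML
#' (golden-section/Brent search on log delta, reusing one spectral
#' decomposition of `K`); every non-cofactor SNP is then tested as a
#' fixed effect by a generalized-least-squares Wald test in the rotated
#' space. The minimum-p SNP is added as a cofactor while its p-value is
#' below the Bonferroni threshold `alpha / m`; a backward pass removes
#' cofactors whose p-value rises above the threshold. Markers below
#' `maf_min` are excluded first.
#'
#' @param panel complete [genotype_panel()].
#' @param y named numeric vector or tibble (`genotype`, `lsmean`) of
#'   phenotypic LS-means indexed by panel individuals.
#' @param K kinship matrix (default [kinship_vanraden()] of `panel`).
#' @param maf_min minor-allele-frequency filter.
#' @param alpha family-wise significance level.
#' @param max_steps maximum forward steps.
#' @param merge_window_bp window for [merge_regions()].
#' @param eig optional precomputed `eigen(K, symmetric = TRUE)`.
#' @return object of class `gwas_scan`: per-SNP tibble (`marker`,
#'   `chrom`, `pos`, `maf`, `p`, `step`, `is_cofactor`, `r2` for
#'   significant SNPs), `cofactors`, `alpha_star`, `m`, `regions`,
#'   `n_regions`, `delta` (per step), `n_skipped_collinear`.
#' @export
mlmm_scan <- function(panel, y, K = NULL, maf_min = 0.05, alpha = 0.05,
                      max_steps = 10, merge_window_bp = 1e6, eig = NULL) {
  if (is.data.frame(y)) y <- stats::setNames(y$lsmean, y$genotype)
  ids <- rownames(panel$dosage)
  if (!all(ids %in% names(y))) stop("y must cover all panel individuals", call. = FALSE)
  yv <- as.numeric(y[ids])
  keep <- panel_maf(panel) >= maf_min
  G <- panel$dosage[, keep, drop = FALSE]
  map <- panel$map[keep, ]
  n <- length(yv); m <- ncol(G)
  alpha_star <- alpha / m
  if (is.null(K) && is.null(eig)) K <- kinship_vanraden(panel)
  if (is.null(eig)) eig <- eigen(K, symmetric = TRUE)
  S <- pmax(eig$values, 0)
  U <- eig$vectors
  yr <- as.numeric(crossprod(U, yv))
  Gr <- crossprod(U, G)                      # rotated SNPs, reused all steps
  onesr <- crossprod(U, rep(1, n))

  cof <- integer(0)
  p_last <- rep(NA_real_, m)
  step_last <- rep(NA_integer_, m)
  deltas <- numeric(0)
  n_skip <- 0L

  test_all <- function(Xr, delta, cols) {
    w <- sqrt(1 / (S + delta))
    Xw <- Xr * w; yw <- yr * w
    qrX <- qr(Xw)
    ry <- qr.resid(qrX, yw)
    rss0 <- sum(ry^2)
    Gw <- Gr[, cols, drop = FALSE] * w
    Rg <- qr.resid(qrX, Gw)
    ss <- colSums(Rg^2)
    ok <- ss > 1e-10
    b <- rep(NA_real_, length(cols))
    b[ok] <- colSums(Rg[, ok, drop = FALSE] * ry) / ss[ok]
    rssj <- rss0 - b^2 * ss
    df <- n - ncol(Xr) - 1
    t2 <- b^2 * ss * df / rssj
    p <- rep(NA_real_, length(cols))
    p[ok] <- 2 * stats::pt(sqrt(t2[ok]), df, lower.tail = FALSE)
    list(p = p, n_skip = sum(!ok))
  }

  for (step in seq_len(max_steps)) {
    Xr <- cbind(onesr, Gr[, cof, drop = FALSE])
    delta <- reml_delta(yr, Xr, S)
    deltas <- c(deltas, delta)
    cols <- setdiff(seq_len(m), cof)
    tt <- test_all(Xr, delta, cols)
    n_skip <- n_skip + tt$n_skip
    p_last[cols] <- tt$p
    step_last[cols] <- step
    if (all(is.na(tt$p))) break
    j <- cols[which.min(tt$p)]
    if (min(tt$p, na.rm = TRUE) < alpha_star) {
      cof <- c(cof, j)
    } else break
  }

  # backward pass: re-test each cofactor within the final model
  if (length(cof) > 0) {
    final_step <- length(deltas)
    repeat {
      dropped <- FALSE
      for (j in cof) {
        others <- setdiff(cof, j)
        Xr <- cbind(onesr, Gr[, others, drop = FALSE])
        delta <- reml_delta(yr, Xr, S)
        tt <- test_all(Xr, delta, j)
        p_last[j] <- tt$p
        step_last[j] <- final_step
        if (is.na(tt$p) || tt$p >= alpha_star) {
          cof <- others; dropped <- TRUE; break
        }
      }
      if (!dropped || length(cof) == 0) break
    }
  }

  sig <- which(!is.na(p_last) & p_last < alpha_star)
  r2 <- rep(NA_real_, m)
  for (j in sig) r2[j] <- snp_r2(G[, j], yv)
  scan <- tibble::tibble(marker = map$marker, chrom = map$chrom, pos = map$pos,
                         maf = panel_maf(panel)[keep], p = p_last,
                         step = step_last,
                         is_cofactor = seq_len(m) %in% cof, r2 = r2)
  regions <- merge_regions(scan[sig, ], merge_window_bp = merge_window_bp)
  structure(list(scan = scan, cofactors = map$marker[cof],
                 alpha_star = alpha_star, m = m, regions = regions,
                 n_regions = nrow(regions), delta = deltas,
                 n_skipped_collinear = n_skip),
            class = "gwas_scan")
}

#' @export
print.gwas_scan <- function(x, ...) {
  cat("<gwas_scan> ", x$m, " SNPs tested, Bonferroni alpha* = ",
      format(x$alpha_star, digits = 3), "\n", sep = "")
  cat("  cofactors:", if (length(x$cofactors)) paste(x$cofactors, collapse = ", ")
      else "none", "\n")
  cat("  significant regions:", x$n_regions, "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.gwas_scan <- function(x, ...) x$scan

#' @exportS3Method generics::glance
glance.gwas_scan <- function(x, ...) {
  tibble::tibble(m = x$m, alpha_star = x$alpha_star,
                 n_cofactors = length(x$cofactors), n_regions = x$n_regions,
                 delta_final = utils::tail(x$delta, 1))
}

#' Manhattan plot of a GWAS scan
#' @param object a `gwas_scan`.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.gwas_scan <- function(object, ...) {
  d <- dplyr::mutate(object$scan,
                     chrom_n = as.integer(factor(chrom, levels = unique(chrom))))
  ggplot2::ggplot(d, ggplot2::aes(pos / 1e6, -log10(p),
                                  colour = factor(chrom_n %% 2))) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::facet_grid(~chrom_n, scales = "free_x", space = "free_x") +
    ggplot2::geom_hline(yintercept = -log10(object$alpha_star), linetype = 2) +
    ggplot2::labs(x = "position (Mb)", y = expression(-log[10](p)))
}

#' Merge significant SNPs into regions
#'
#' Significant SNPs on the same chromosome within `merge_window_bp` of
#' the running region are merged; the region count is the paper-style
#' "number of significant associations".
#'
#' @param sig tibble of significant SNPs (`marker`, `chrom`, `pos`,
#'   optionally `p`).
#' @param merge_window_bp merging window.
#' @return tibble `chrom`, `start`, `end`, `n_snps`, `best_snp`.
#' @export
merge_regions <- function(sig, merge_window_bp = 1e6) {
  if (nrow(sig) == 0) {
    return(tibble::tibble(chrom = character(0), start = numeric(0),
                          end = numeric(0), n_snps = integer(0),
                          best_snp = character(0)))
  }
  sig <- dplyr::arrange(sig, chrom, pos)
  out <- list()
  cur <- sig[1, ]
  cur_rows <- sig[1, ]
  flush <- function(rows) {
    best <- if ("p" %in% names(rows) && !all(is.na(rows$p))) {
      rows$marker[which.min(rows$p)]
    } else rows$marker[1]
    tibble::tibble(chrom = rows$chrom[1], start = min(rows$pos),
                   end = max(rows$pos), n_snps = nrow(rows), best_snp = best)
  }
  if (nrow(sig) > 1) {
    for (i in 2:nrow(sig)) {
      same <- sig$chrom[i] == cur_rows$chrom[1] &&
        sig$pos[i] - max(cur_rows$pos) <= merge_window_bp
      if (same) {
        cur_rows <- dplyr::bind_rows(cur_rows, sig[i, ])
      } else {
        out[[length(out) + 1]] <- flush(cur_rows)
        cur_rows <- sig[i, ]
      }
    }
  }
  out[[length(out) + 1]] <- flush(cur_rows)
  dplyr::bind_rows(out)
}

#' Phenotypic variance explained by a single SNP
#'
#' Coefficient of determination of the simple linear regression of the
#' phenotype on the SNP dosage.
#'
#' @param x dosage vector (non-constant).
#' @param y phenotype vector.
#' @return r-squared.
#' @export
snp_r2 <- function(x, y) {
  if (stats::sd(x) == 0) return(NA_real_)
  stats::cor(x, y)^2
}
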