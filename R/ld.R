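#' Squared Pearson correlation between two dosage vectors
#'
#' The genotype-based (composite) LD statistic: no phase is required.
#'
#' @param x,y equal-length dosage vectors.
#' @return r-squared, or `NA` with a warning attribute if either vector
#'   is constant.
#' @export
ld_r2 <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    stop("vectors must have equal length >= 2", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Sample intra-chromosomal marker pairs and score r-squared
#'
#' Within each chromosome a seeded fraction of markers is sampled
#' without replacement (ceiling of `fraction` times the marker count)
#' and all pairs among the sampled markers are scored. Pairs involving a
#' constant marker are dropped and counted.
#'
#' @param panel complete [genotype_panel()].
#' @param fraction fraction of markers sampled per chromosome.
#' @param max_pairs if the pooled pair count exceeds this, a seeded
#'   subsample of pairs is kept (mirrors smoothing on a capped sample).
#' @param seed integer seed.
#' @return tibble of class `ld_pairs`: `chrom`, `marker_i`, `marker_j`,
#'   `dist_bp`, `r2`, with attributes `n_constant_dropped`, `fraction`,
#'   `seed`.
#' @export
ld_sample_pairs <- function(panel, fraction = 0.1, max_pairs = 100000, seed = 1) {
  set.seed(seed)
  dropped <- 0L
  res <- purrr::map_dfr(unique(panel$map$chrom), function(ch) {
    idx <- which(panel$map$chrom == ch)
    k <- ceiling(fraction * length(idx))
    keep <- sort(sample(idx, k))
    sdv <- apply(panel$dosage[, keep, drop = FALSE], 2, stats::sd)
    const <- sdv == 0
    dropped <<- dropped + sum(const) * (k - 1L)
    keep <- keep[!const]
    if (length(keep) < 2) {
      return(tibble::tibble(chrom = character(0), marker_i = character(0),
                            marker_j = character(0), dist_bp = numeric(0),
                            r2 = numeric(0)))
    }
    cm <- stats::cor(panel$dosage[, keep, drop = FALSE])^2
    pr <- which(upper.tri(cm), arr.ind = TRUE)
    tibble::tibble(
      chrom = ch,
      marker_i = panel$map$marker[keep[pr[, 1]]],
      marker_j = panel$map$marker[keep[pr[, 2]]],
      dist_bp = abs(panel$map$pos[keep[pr[, 2]]] - panel$map$pos[keep[pr[, 1]]]),
      r2 = cm[pr]
    )
  })
  if (nrow(res) > max_pairs) res <- res[sort(sample.int(nrow(res), max_pairs)), ]
  attr(res, "n_constant_dropped") <- dropped
  attr(res, "fraction") <- fraction
  attr(res, "seed") <- seed
  class(res) <- c("ld_pairs", class(res))
  res
}

#' LD decay summary: loess curve, 0.2-threshold distance, windowed means
#'
#' Fits a loess smoother (local quadratic, tricube weights,
#' `span = alpha`) of r-squared against distance, evaluates it on a
#' log-spaced grid, reports the first distance at which the fitted curve
#' drops below `threshold` (linear interpolation between grid points),
#' and mean r-squared within a +/-`window_bp` window around each
#' reference distance.
#'
#' @param pairs an `ld_pairs` tibble (or any tibble with `dist_bp`, `r2`).
#' @param alpha loess span.
#' @param threshold r-squared decay threshold.
#' @param ref_distances reference distances (bp) for windowed means.
#' @param window_bp half-width of the averaging window.
#' @param grid_n number of grid points for curve evaluation.
#' @return list of class `ld_decay`: `curve` (tibble `dist_bp`,
#'   `r2_fit`), `threshold_dist_bp` (`NA` if never crossed),
#'   `window_means` (tibble `ref_bp`, `mean_r2`, `n_pairs`).
#' @export
ld_decay <- function(pairs, alpha = 0.5, threshold = 0.2,
                     ref_distances = c(100, 1000, 5000, 100000),
                     window_bp = 50, grid_n = 200) {
  if (nrow(pairs) < 50) stop("need at least 50 pairs", call. = FALSE)
  fit <- stats::loess(r2 ~ dist_bp, data = pairs, span = alpha, degree = 2,
                      family = "gaussian",
                      control = stats::loess.control(surface = "interpolate"))
  rng <- range(pairs$dist_bp)
  grid <- exp(seq(log(max(rng[1], 1)), log(rng[2]), length.out = grid_n))
  pred <- stats::predict(fit, newdata = data.frame(dist_bp = grid))
  curve <- tibble::tibble(dist_bp = grid, r2_fit = as.numeric(pred))
  below <- which(!is.na(curve$r2_fit) & curve$r2_fit < threshold)
  th <- NA_real_
  if (length(below)) {
    b <- below[1]
    if (b == 1 || is.na(curve$r2_fit[b - 1])) {
      # already below the threshold at the first evaluable distance
      th <- curve$dist_bp[b]
    } else {
      x0 <- curve$dist_bp[b - 1]; x1 <- curve$dist_bp[b]
      y0 <- curve$r2_fit[b - 1]; y1 <- curve$r2_fit[b]
      th <- x0 + (threshold - y0) * (x1 - x0) / (y1 - y0)
    }
  }
  wm <- purrr::map_dfr(ref_distances, function(d) {
    sel <- abs(pairs$dist_bp - d) <= window_bp
    tibble::tibble(ref_bp = d,
                   mean_r2 = if (any(sel)) mean(pairs$r2[sel]) else NA_real_,
                   n_pairs = sum(sel))
  })
  structure(list(curve = curve, threshold = threshold,
                 threshold_dist_bp = th, window_means = wm, span = alpha),
            class = "ld_decay")
}

#' @export
print.ld_decay <- function(x, ...) {
  cat("<ld_decay> span =", x$span, "\n")
  if (is.na(x$threshold_dist_bp)) {
    cat("  fitted curve never drops below", x$threshold, "\n")
  } else {
    cat("  r2 drops below", x$threshold, "at",
        round(x$threshold_dist_bp), "bp\n")
  }
  print(x$window_means)
  invisible(x)
}

#' Sliding-window LD pruning
#'
#' Greedy removal in windows of `window` markers advanced by `step`
#' markers (map order): while any retained pair within the window has
#' r-squared above `r2_max`, the later marker of the offending pair is
#' removed. Ties keep the earlier marker; the procedure is
#' deterministic.
#'
#' @param panel complete [genotype_panel()].
#' @param window window size in markers.
#' @param step window advance in markers.
#' @param r2_max pruning threshold.
#' @return integer vector of retained marker indices (map order).
#' @export
ld_prune <- function(panel, window = 50, step = 10, r2_max = 0.1) {
  M <- ncol(panel$dosage)
  keep <- rep(TRUE, M)
  for (ch in unique(panel$map$chrom)) {
    idx <- which(panel$map$chrom == ch)
    starts <- seq(1, max(1, length(idx) - 1), by = step)
    for (s in starts) {
      win <- idx[s:min(s + window - 1, length(idx))]
      win <- win[keep[win]]
      if (length(win) < 2) next
      cm <- suppressWarnings(stats::cor(panel$dosage[, win, drop = FALSE])^2)
      cm[is.na(cm)] <- 0
      repeat {
        cm[lower.tri(cm, diag = TRUE)] <- 0
        off <- which(cm > r2_max, arr.ind = TRUE)
        if (nrow(off) == 0) break
        # remove the later marker of the first offending pair
        off <- off[order(off[, 1], off[, 2]), , drop = FALSE]
        drop_local <- max(off[1, ])
        keep[win[drop_local]] <- FALSE
        cm <- cm[-drop_local, -drop_local, drop = FALSE]
        win <- win[-drop_local]
        if (length(win) < 2) break
      }
    }
  }
  which(keep)
}

#' Plot an LD decay summary
#' @param object an `ld_decay` object.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ld_decay <- function(object, ...) {
  p <- ggplot2::ggplot(object$curve, ggplot2::aes(dist_bp, r2_fit)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = 2) +
    ggplot2::labs(x = "distance (bp)", y = expression(fitted ~ r^2))
  if (!is.na(object$threshold_dist_bp)) {
    p <- p + ggplot2::geom_vline(xintercept = object$threshold_dist_bp,
                                 linetype = 3)
  }
  p
}
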