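#' Family-based imputation from scaffold to full marker density
#'
#' Traces which parental haplotype each offspring transmitted along each
#' chromosome with a minimal-switch dynamic program over the scaffold
#' markers: states are the four (maternal haplotype, paternal haplotype)
#' combinations, a haplotype switch costs `switch_penalty` and a
#' genotype mismatch costs `mismatch_cost` (defaults make one crossover
#' cheaper than two genotyping errors). Dense expected dosage is the sum
#' of expected transmitted alleles; where the optimal assignment is
#' ambiguous all optimal states are weighted equally. Scaffold markers
#' pass through unchanged. Scaffold genotypes incompatible with both
#' parents under every state (opposing homozygotes) are flagged and
#' excluded from the trace.
#'
#' @param haps phased `haplotype_set` containing both parents at full
#'   density.
#' @param mother,father parent ids.
#' @param offspring_dosage matrix (offspring x scaffold markers) of
#'   observed scaffold dosages.
#' @param scaffold_index integer positions of the scaffold markers in
#'   the full map.
#' @param switch_penalty cost per haplotype switch.
#' @param mismatch_cost cost per scaffold genotype mismatch.
#' @param round_dosage return hard 0/1/2 calls instead of expected dosage.
#' @return list with `imputed` (offspring x full markers expected dosage)
#'   and `flagged` (tibble of excluded Mendelian-inconsistent cells).
#' @export
impute_family <- function(haps, mother, father, offspring_dosage,
                          scaffold_index, switch_penalty = 2,
                          mismatch_cost = 1.5, round_dosage = FALSE) {
  stopifnot(inherits(haps, "haplotype_set"))
  map <- haps$map
  M <- nrow(map)
  mh <- rbind(haps$H1[mother, ], haps$H2[mother, ])
  fh <- rbind(haps$H1[father, ], haps$H2[father, ])
  k <- nrow(offspring_dosage)
  imputed <- matrix(NA_real_, k, M,
                    dimnames = list(rownames(offspring_dosage), map$marker))
  flagged <- list()
  # state s = (i, j): maternal hap i, paternal hap j
  st <- expand.grid(i = 1:2, j = 1:2)

  for (o in seq_len(k)) {
    obs_full <- rep(NA_real_, M)
    obs_full[scaffold_index] <- offspring_dosage[o, ]
    for (ch in unique(map$chrom)) {
      loci <- which(map$chrom == ch)
      anchors <- intersect(scaffold_index, loci)
      anchors <- anchors[!is.na(obs_full[anchors])]
      if (length(anchors) > 0) {
        # emission cost matrix anchors x 4
        em <- vapply(seq_len(4), function(s) {
          pred <- mh[st$i[s], anchors] + fh[st$j[s], anchors]
          ifelse(pred == obs_full[anchors], 0, mismatch_cost)
        }, numeric(length(anchors)))
        if (length(anchors) == 1) em <- matrix(em, nrow = 1)
        incons <- rowSums(em == 0) == 0
        if (any(incons)) {
          flagged[[length(flagged) + 1]] <- tibble::tibble(
            offspring = rownames(offspring_dosage)[o],
            marker = map$marker[anchors[incons]])
          anchors <- anchors[!incons]
          em <- em[!incons, , drop = FALSE]
        }
      }
      if (length(anchors) == 0) {
        imputed[o, loci] <- (mh[1, loci] + mh[2, loci]) / 2 +
          (fh[1, loci] + fh[2, loci]) / 2
        next
      }
      Tn <- length(anchors)
      trans <- outer(seq_len(4), seq_len(4), function(a, b) {
        switch_penalty * ((st$i[a] != st$i[b]) + (st$j[a] != st$j[b]))
      })
      Fm <- matrix(0, Tn, 4); Bm <- matrix(0, Tn, 4)
      Fm[1, ] <- em[1, ]
      if (Tn > 1) {
        for (t in 2:Tn) {
          Fm[t, ] <- em[t, ] + apply(Fm[t - 1, ] + trans, 2, min)
        }
        for (t in (Tn - 1):1) {
          Bm[t, ] <- apply(trans + rep(Bm[t + 1, ] + em[t + 1, ], each = 4), 1, min)
        }
      }
      total <- Fm + Bm
      best <- min(Fm[Tn, ])
      opt <- total <= best + 1e-9
      # per anchor: probability that maternal hap 1 / paternal hap 1 is
      # transmitted, averaged over optimal states
      pm1 <- rowSums(opt[, st$i == 1, drop = FALSE]) / rowSums(opt)
      pf1 <- rowSums(opt[, st$j == 1, drop = FALSE]) / rowSums(opt)

      a_in_chr <- match(anchors, loci)
      left <- findInterval(seq_along(loci), a_in_chr)
      right <- pmin(left + 1L, Tn)
      left_c <- pmax(left, 1L)
      exp_allele <- function(p1, hap) {
        pl <- p1[left_c] * hap[1, loci] + (1 - p1[left_c]) * hap[2, loci]
        pr <- p1[right] * hap[1, loci] + (1 - p1[right]) * hap[2, loci]
        wl <- ifelse(left == 0, 0, 0.5); wr <- ifelse(left == 0, 1, 0.5)
        at_anchor <- seq_along(loci) %in% a_in_chr
        out <- wl * pl + wr * pr
        out[at_anchor] <- pl[at_anchor]   # exactly on an anchor: its own state
        out
      }
      dose <- exp_allele(pm1, mh) + exp_allele(pf1, fh)
      imputed[o, loci] <- dose
      seen <- anchors
      imputed[o, seen] <- obs_full[seen]  # scaffold pass-through
    }
  }
  if (round_dosage) imputed <- pmin(2, pmax(0, round(imputed)))
  list(imputed = imputed,
       flagged = if (length(flagged)) dplyr::bind_rows(flagged)
                 else tibble::tibble(offspring = character(0), marker = character(0)))
}

#' Impute every full-sib family in a pedigree
#'
#' @param haps phased founder `haplotype_set` at full density.
#' @param scaffold scaffold-tier [genotype_panel()] of the progeny.
#' @param pedigree tibble `id`, `mother`, `father` covering the progeny.
#' @param scaffold_index positions of scaffold markers in the full map.
#' @param ... passed to [impute_family()].
#' @return list as in [impute_family()], rows ordered as in `scaffold`.
#' @export
impute_pedigree <- function(haps, scaffold, pedigree, scaffold_index, ...) {
  prog <- pedigree[!is.na(pedigree$mother) & !is.na(pedigree$father), ]
  prog <- prog[prog$id %in% rownames(scaffold$dosage), ]
  fams <- dplyr::group_split(dplyr::group_by(prog, mother, father))
  res <- purrr::map(fams, function(f) {
    impute_family(haps, f$mother[1], f$father[1],
                  scaffold$dosage[f$id, , drop = FALSE], scaffold_index, ...)
  })
  imputed <- do.call(rbind, purrr::map(res, "imputed"))
  imputed <- imputed[intersect(rownames(scaffold$dosage), rownames(imputed)), ,
                     drop = FALSE]
  list(imputed = imputed, flagged = dplyr::bind_rows(purrr::map(res, "flagged")))
}

row_col_cor <- function(imp, truth, margin) {
  n <- dim(truth)[margin]
  r <- numeric(n); ok <- logical(n)
  for (i in seq_len(n)) {
    a <- if (margin == 1) imp[i, ] else imp[, i]
    b <- if (margin == 1) truth[i, ] else truth[, i]
    keep <- !is.na(a) & !is.na(b)
    if (sum(keep) >= 2 && stats::sd(a[keep]) > 0 && stats::sd(b[keep]) > 0) {
      r[i] <- stats::cor(a[keep], b[keep]); ok[i] <- TRUE
    }
  }
  list(r = r[ok], n_undefined = sum(!ok))
}

#' Imputation accuracy: Pearson correlation across individuals and markers
#'
#' "Across individuals" is the mean over individuals of the Pearson
#' correlation between that individual's imputed and true dosages over
#' markers; "across markers" is the mean over markers of the
#' per-marker correlation over individuals. Zero-variance rows/columns
#' give undefined correlations; they are excluded from the means and
#' counted, not coerced to 0.
#'
#' @param imputed,truth equally shaped dosage matrices (individuals x
#'   markers); `truth` must be complete.
#' @return tibble with one row: `acc_individuals`, `acc_markers`,
#'   `n_undefined_individuals`, `n_undefined_markers`.
#' @export
imputation_accuracy <- function(imputed, truth) {
  if (!all(dim(imputed) == dim(truth))) stop("shape mismatch", call. = FALSE)
  bi <- row_col_cor(imputed, truth, 1)
  bm <- row_col_cor(imputed, truth, 2)
  tibble::tibble(
    acc_individuals = if (length(bi$r)) mean(bi$r) else NA_real_,
    acc_markers = if (length(bm$r)) mean(bm$r) else NA_real_,
    n_undefined_individuals = bi$n_undefined,
    n_undefined_markers = bm$n_undefined
  )
}

#' Percentage of marker values newly inferred by imputation
#'
#' @param scaffold_size observed (low-density) marker count.
#' @param full_size full-density marker count.
#' @return percentage `100 * (full - scaffold) / full`.
#' @export
fraction_imputed <- function(scaffold_size, full_size) {
  if (scaffold_size > full_size) stop("scaffold_size > full_size", call. = FALSE)
  100 * (full_size - scaffold_size) / full_size
}
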