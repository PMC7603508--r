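#' Evenly spaced marker subset from a random starting point
#'
#' Marker order along the map is used as a proxy for physical distance:
#' with stride `floor(M/m)`, the subset takes indices congruent to a
#' seeded random start modulo the stride, truncated from the end to
#' exactly `m` markers.
#'
#' @param M total marker count (or a [genotype_panel()]).
#' @param m subset size.
#' @param seed integer seed for the random start.
#' @param start optional explicit 0-based start (overrides the seed).
#' @return sorted integer vector of `m` marker indices (1-based).
#' @export
evenly_spaced_subset <- function(M, m, seed = 1, start = NULL) {
  if (inherits(M, "genotype_panel")) M <- ncol(M$dosage)
  if (m > M) stop("subset larger than panel", call. = FALSE)
  stride <- M %/% m
  if (stride <= 1) stride <- 1
  if (is.null(start)) {
    set.seed(seed)
    start <- sample.int(stride, 1) - 1L
  }
  idx <- seq(start + 1L, M, by = stride)
  idx[seq_len(m)]
}

#' SNP-density x feature-selection experiment
#'
#' Reruns the GWAS scan and genomic-prediction cross-validation over
#' marker subsets: seeded evenly spaced subsets at each density, plus
#' (optionally) the scaffold-array panel and the LD-thinned panel, each
#' evaluated once. Kinship for the mixed model always comes from the
#' full panel so that density varies only the tested markers; the
#' Bonferroni denominator adapts to the subset size.
#'
#' @param panel full-density [genotype_panel()].
#' @param y LS-means vector or tibble (`genotype`, `lsmean`).
#' @param densities marker counts to test (truncated to the panel size).
#' @param seeds_per_density number of random starts per density.
#' @param cv_repetitions,folds cross-validation settings per subset.
#' @param scaffold_index optional scaffold marker indices (strategy
#'   `scaffold_panel`).
#' @param ld_pruned optional LD-pruned marker indices (strategy
#'   `ld_thinned`).
#' @param seed master seed.
#' @param do_gwas run the association scan per subset.
#' @param ... further arguments to [mlmm_scan()].
#' @return object of class `density_grid`: `results` (tibble `strategy`,
#'   `density`, `seed`, `n_regions`, `ability`), `summary` (per
#'   strategy x density mean and normal-approximation 95% CI over
#'   seeds).
#' @export
density_grid <- function(panel, y,
                         densities = c(500, 1000, 5000, 10000, 50000, 1e5,
                                       15e4, 2e5, 25e4),
                         seeds_per_density = 10, cv_repetitions = 10,
                         folds = 5, scaffold_index = NULL, ld_pruned = NULL,
                         seed = 1, do_gwas = TRUE, ...) {
  M <- ncol(panel$dosage)
  densities <- unique(pmin(densities[densities <= M], M))
  K <- kinship_vanraden(panel)
  eig <- eigen(K, symmetric = TRUE)
  if (is.data.frame(y)) y <- stats::setNames(y$lsmean, y$genotype)

  run_subset <- function(idx, strategy, density, sub_seed) {
    sub <- subset_panel(panel, markers = idx)
    nreg <- NA_integer_
    if (do_gwas) {
      scan <- mlmm_scan(sub, y, eig = eig, ...)
      nreg <- scan$n_regions
    }
    cv <- cross_validate(sub, y, folds = folds,
                         repetitions = cv_repetitions, seed = sub_seed)
    tibble::tibble(strategy = strategy, density = density, seed = sub_seed,
                   n_regions = nreg, ability = cv$ability)
  }

  res <- list()
  k <- 0L
  for (d in densities) {
    for (s in seq_len(seeds_per_density)) {
      k <- k + 1L
      sub_seed <- (seed * 1000L + k * 97L) %% .Machine$integer.max
      idx <- evenly_spaced_subset(M, d, seed = sub_seed)
      res[[length(res) + 1]] <- run_subset(idx, "evenly_spaced", d, sub_seed)
    }
  }
  if (!is.null(scaffold_index)) {
    res[[length(res) + 1]] <- run_subset(scaffold_index, "scaffold_panel",
                                         length(scaffold_index), seed)
  }
  if (!is.null(ld_pruned)) {
    res[[length(res) + 1]] <- run_subset(ld_pruned, "ld_thinned",
                                         length(ld_pruned), seed)
  }
  results <- dplyr::bind_rows(res)
  summary <- results |>
    dplyr::group_by(strategy, density) |>
    dplyr::summarise(
      n_seeds = dplyr::n(),
      mean_regions = mean(n_regions),
      mean_ability = mean(ability),
      se_ability = ifelse(dplyr::n() > 1, stats::sd(ability) / sqrt(dplyr::n()), NA),
      se_regions = ifelse(dplyr::n() > 1, stats::sd(n_regions) / sqrt(dplyr::n()), NA),
      .groups = "drop") |>
    dplyr::mutate(
      ability_lo = mean_ability - 1.96 * se_ability,
      ability_hi = mean_ability + 1.96 * se_ability,
      regions_lo = mean_regions - 1.96 * se_regions,
      regions_hi = mean_regions + 1.96 * se_regions)
  structure(list(results = results, summary = summary, seed = seed),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat("<density_grid>\n")
  print(x$summary)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.density_grid <- function(x, ...) x$results

#' Plot predictive ability against SNP density
#' @param object a `density_grid`.
#' @param ... unused.
#' @return a ggplot with 95% CI ribbons where available.
#' @exportS3Method ggplot2::autoplot
autoplot.density_grid <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(density, mean_ability, colour = strategy)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = ability_lo, ymax = ability_hi),
                           width = 0.05, na.rm = TRUE) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "SNP density", y = "mean predictive ability")
}
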