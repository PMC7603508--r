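#' Closed-form expected precision of genomic estimated breeding values
#'
#' `r2_hat = N h2 / (N h2 + M (1 - h2))`, with `N` the training
#' population size, `M` the number of loci in LD with the genes
#' underlying the trait, and `h2` the heritability. The formula is
#' scale-invariant in (N, M) and strictly monotone in each argument.
#' `M = 0` returns 1 (no unlinked noise loci); `h2 = 0` returns 0 with a
#' warning.
#'
#' @param N training population size (>= 1); vectorized.
#' @param M number of effective loci (>= 0); vectorized.
#' @param h2 heritability in (0, 1]; vectorized.
#' @return expected precision in (0, 1].
#' @export
gebv_precision <- function(N, M, h2) {
  if (any(N < 1)) stop("N must be >= 1", call. = FALSE)
  if (any(M < 0)) stop("M must be >= 0", call. = FALSE)
  if (any(h2 < 0 | h2 > 1)) stop("h2 must be in [0, 1]", call. = FALSE)
  if (any(h2 == 0)) warning("h2 = 0: precision defined as 0")
  ifelse(h2 == 0, 0, N * h2 / (N * h2 + M * (1 - h2)))
}

#' Trait-architecture classes from the number of effective loci
#'
#' `oligogenic` (M <= 10), `complex` (10 < M <= 100), `very complex`
#' (100 < M <= 1000), `beyond` (M > 1000); total and disjoint.
#'
#' @param M numeric vector of effective locus counts.
#' @return factor of class labels.
#' @export
classify_architecture <- function(M) {
  cut(M, breaks = c(-Inf, 10, 100, 1000, Inf),
      labels = c("oligogenic", "complex", "very complex", "beyond"))
}

#' Precision grid over design parameters
#'
#' Evaluates [gebv_precision()] over training sizes, a log grid of
#' effective locus counts and heritability levels, labelling each point
#' with its architecture class and whether precision is very high
#' (>= `very_high`).
#'
#' @param N_list training sizes.
#' @param M_range range of effective loci (log-spaced grid of
#'   `M_points` values).
#' @param h2_list heritabilities.
#' @param M_points grid resolution.
#' @param very_high threshold flagging very high precision.
#' @return tibble `N`, `M`, `h2`, `precision`, `architecture`,
#'   `very_high`, of class `precision_grid`.
#' @export
precision_grid <- function(N_list = c(10, 269, 534, 1000),
                           M_range = c(1, 1e6), h2_list = c(0.5, 0.8),
                           M_points = 121, very_high = 0.8) {
  M <- unique(round(exp(seq(log(M_range[1]), log(M_range[2]),
                            length.out = M_points))))
  grid <- tidyr::expand_grid(N = N_list, M = M, h2 = h2_list)
  out <- grid |>
    dplyr::mutate(precision = gebv_precision(N, M, h2),
                  architecture = classify_architecture(M),
                  very_high = precision >= very_high)
  class(out) <- c("precision_grid", class(out))
  out
}

#' Plot a precision grid
#' @param object a `precision_grid` tibble.
#' @param ... unused.
#' @return a ggplot of precision against M per N, faceted by h2.
#' @exportS3Method ggplot2::autoplot
autoplot.precision_grid <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(M, precision, colour = factor(N))) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.8, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~h2, labeller = ggplot2::label_both) +
    ggplot2::labs(colour = "N", y = "expected precision of GEBVs")
}
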