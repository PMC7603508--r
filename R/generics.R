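#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
#' @importFrom stats cor sd var
NULL

utils::globalVariables(c(
  "genotype", "environment", "block", "row", "col", "trait", "value",
  "marker", "chrom", "pos", "r2", "dist_bp", "r2_fit", "p", "chrom_n",
  "PC1", "PC2", "group", "ability", "density", "strategy", "n_regions",
  "mean_ability", "ability_lo", "ability_hi", "mean_regions",
  "se_ability", "se_regions", "n", "pred", "lsmean", "precision", "M",
  "h2", "N", "surface", "mother", "father", "n_offspring", "family",
  "environment"))
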