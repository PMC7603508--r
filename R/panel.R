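#' Genotype panel container
#'
#' Bundles a dosage matrix (individuals x markers, allele counts in
#' \{0, 1, 2\}, `NA` allowed only on scaffold-tier panels), a marker map and
#' per-individual metadata. This is the object every downstream stage
#' (imputation, LD, structure, GWAS, prediction) consumes.
#'
#' @param dosage numeric matrix, individuals in rows, markers in columns.
#'   Row names are individual ids, column names marker ids.
#' @param map tibble with columns `marker`, `chrom`, `pos` (1-based bp),
#'   sorted by (`chrom`, `pos`) and matching the columns of `dosage`.
#' @param info tibble with one row per individual: `id`, `group`
#'   (`"accession"` or `"progeny"`) and `origin` label. Defaults to
#'   accessions of unknown origin.
#' @param tier `"full"` or `"scaffold"` marker-density tier.
#'
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(dosage, map, info = NULL, tier = c("full", "scaffold")) {
  tier <- match.arg(tier)
  stopifnot(is.matrix(dosage))
  map <- tibble::as_tibble(map)
  if (!all(c("marker", "chrom", "pos") %in% names(map))) {
    stop("map must have columns marker, chrom, pos", call. = FALSE)
  }
  if (nrow(map) != ncol(dosage)) {
    stop("map rows (", nrow(map), ") != dosage columns (", ncol(dosage), ")",
         call. = FALSE)
  }
  ord <- order(suppressWarnings(as.integer(map$chrom)), map$pos)
  if (is.unsorted(ord)) stop("marker map must be sorted by (chrom, pos)", call. = FALSE)
  if (is.null(rownames(dosage))) rownames(dosage) <- paste0("ind", seq_len(nrow(dosage)))
  if (anyDuplicated(rownames(dosage))) stop("individual ids must be unique", call. = FALSE)
  colnames(dosage) <- map$marker
  if (is.null(info)) {
    info <- tibble::tibble(id = rownames(dosage), group = "accession", origin = "U")
  }
  info <- tibble::as_tibble(info)
  if (!identical(info$id, rownames(dosage))) {
    stop("info$id must match dosage row names in order", call. = FALSE)
  }
  bad <- dosage[!is.na(dosage) & !(dosage %in% 0:2)]
  if (length(bad)) stop("dosage values must be 0, 1 or 2", call. = FALSE)
  if (tier == "full" && anyNA(dosage)) {
    stop("missing dosage is only legal on scaffold-tier panels", call. = FALSE)
  }
  structure(
    list(dosage = dosage, map = map, info = info, tier = tier),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("<genotype_panel> ", nrow(x$dosage), " individuals x ", ncol(x$dosage),
      " markers (", x$tier, " tier, ",
      length(unique(x$map$chrom)), " chromosomes)\n", sep = "")
  grp <- table(x$info$group)
  cat("  groups:", paste(names(grp), grp, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$dosage)

#' Extract the dosage matrix of a panel
#' @param panel a [genotype_panel()].
#' @return numeric matrix, individuals x markers.
#' @export
dosage <- function(panel) panel$dosage

#' Marker map of a panel as a tibble
#' @param panel a [genotype_panel()].
#' @return tibble with `marker`, `chrom`, `pos`.
#' @export
marker_map <- function(panel) panel$map

#' Per-marker minor allele frequency
#' @param panel a [genotype_panel()].
#' @return numeric vector of MAFs, one per marker.
#' @export
panel_maf <- function(panel) {
  p <- colMeans(panel$dosage, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' Subset a panel by marker index or by individual id
#'
#' @param panel a [genotype_panel()].
#' @param markers integer indices (map order) of markers to keep; `NULL`
#'   keeps all.
#' @param individuals character ids or integer indices of individuals to
#'   keep; `NULL` keeps all.
#' @param tier optional tier override for the result.
#' @return a new [genotype_panel()].
#' @export
subset_panel <- function(panel, markers = NULL, individuals = NULL, tier = NULL) {
  if (is.null(markers)) markers <- seq_len(ncol(panel$dosage))
  if (is.null(individuals)) individuals <- seq_len(nrow(panel$dosage))
  if (is.character(individuals)) {
    individuals <- match(individuals, rownames(panel$dosage))
    if (anyNA(individuals)) stop("unknown individual id", call. = FALSE)
  }
  genotype_panel(
    dosage = panel$dosage[individuals, markers, drop = FALSE],
    map = panel$map[markers, ],
    info = panel$info[individuals, ],
    tier = if (is.null(tier)) panel$tier else tier
  )
}
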