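#' Write a genotype panel as a GT-only VCF
#'
#' Emits a minimal VCFv4.2 with one GT-only sample column per individual.
#' Founder/phased genotypes can be written with the `|` separator via
#' `phased`; otherwise `/` is used. Dosage 0/1/2 maps to `0/0`, `0/1`,
#' `1/1`; `NA` maps to `./.`. The writer is deterministic.
#'
#' @param panel a [genotype_panel()].
#' @param path output file.
#' @param phased logical, write phased separators.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(panel, path, phased = FALSE) {
  sep <- if (phased) "|" else "/"
  gt_code <- c("0" = paste0("0", sep, "0"), "1" = paste0("0", sep, "1"),
               "2" = paste0("1", sep, "1"))
  contigs <- unique(panel$map$chrom)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=orchardgp",
    paste0("##contig=<ID=", contigs, ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(panel$dosage)), collapse = "\t")
  )
  body <- character(0)
  if (ncol(panel$dosage) > 0) {
    gt <- matrix(gt_code[as.character(t(panel$dosage))],
                 nrow = ncol(panel$dosage))         # markers x individuals
    gt[is.na(gt)] <- paste0(".", sep, ".")
    body <- paste(panel$map$chrom, panel$map$pos, panel$map$marker,
                  "A", "G", ".", "PASS", ".", "GT",
                  apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a GT-only VCF into a genotype panel
#'
#' Parsing is delegated to \pkg{vcfR}. Multi-allelic and non-SNP records
#' are rejected with a message reporting the count.
#'
#' @param path VCF file (plain text or gzipped).
#' @param info optional individual metadata tibble (`id`, `group`,
#'   `origin`); defaults are filled in.
#' @param tier density tier of the panel.
#' @return a [genotype_panel()].
#' @export
read_vcf <- function(path, info = NULL, tier = "full") {
  first <- readLines(path, n = 1000L)
  if (!any(!startsWith(first, "#") & nzchar(first))) {
    # header-only file (no variant records): recover sample ids by hand
    chrom_line <- first[startsWith(first, "#CHROM")]
    if (length(chrom_line) == 0) stop("malformed VCF: no #CHROM line", call. = FALSE)
    f <- strsplit(chrom_line[1], "\t")[[1]]
    ids <- if (length(f) > 9) f[-(1:9)] else character(0)
    dos <- matrix(numeric(0), nrow = length(ids), ncol = 0,
                  dimnames = list(ids, NULL))
    return(genotype_panel(dos, tibble::tibble(marker = character(0),
                                              chrom = character(0),
                                              pos = integer(0)),
                          info = info, tier = tier))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  keep <- nchar(fix[, "REF"]) == 1 & nchar(fix[, "ALT"]) == 1 &
    !grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(!keep)) {
    message("read_vcf: rejected ", sum(!keep), " multi-allelic/non-SNP records")
  }
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  alt_count <- function(x) {
    a <- strsplit(gsub("\\|", "/", x), "/", fixed = FALSE)
    vapply(a, function(al) {
      if (length(al) == 0 || anyNA(al) || any(al == ".")) return(NA_real_)
      sum(as.integer(al))
    }, numeric(1))
  }
  gt[is.na(gt)] <- "."
  dos <- matrix(alt_count(as.vector(gt)), nrow = nrow(gt))  # markers x inds
  dos <- t(dos)
  rownames(dos) <- colnames(gt)
  map <- tibble::tibble(marker = unname(fix[keep, "ID"]),
                        chrom = unname(fix[keep, "CHROM"]),
                        pos = as.integer(unname(fix[keep, "POS"])))
  genotype_panel(dos, map, info = info, tier = tier)
}

#' Write / read the marker map as TSV
#' @param map tibble with `marker`, `chrom`, `pos`.
#' @param path file path.
#' @return `path` (writer) or the map tibble (reader).
#' @export
write_marker_map <- function(map, path) {
  readr::write_tsv(map, path)
  invisible(path)
}

#' @rdname write_marker_map
#' @export
read_marker_map <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    marker = readr::col_character(), chrom = readr::col_character(),
    pos = readr::col_integer()))
}

#' Write a pedigree as 3-column TSV
#' @param pedigree tibble with `id`, `mother`, `father` (`NA` for founders).
#' @param path file path.
#' @export
write_pedigree <- function(pedigree, path) {
  readr::write_tsv(pedigree, path, na = "")
  invisible(path)
}

#' Read and validate a 3-column pedigree TSV
#'
#' Checks id uniqueness, that every named parent exists, and acyclicity;
#' a cycle is reported with the ids involved. Rows are returned in a
#' topological order (parents before offspring).
#'
#' @param path file path.
#' @return tibble `id`, `mother`, `father`, topologically sorted.
#' @export
read_pedigree <- function(path) {
  ped <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = c("", "NA"))
  if (!all(c("id", "mother", "father") %in% names(ped))) {
    stop("pedigree must have columns id, mother, father", call. = FALSE)
  }
  validate_pedigree(ped)
}

#' @rdname read_pedigree
#' @param ped in-memory pedigree tibble to validate/sort.
#' @export
validate_pedigree <- function(ped) {
  if (anyDuplicated(ped$id)) {
    stop("duplicated pedigree ids: ",
         paste(unique(ped$id[duplicated(ped$id)]), collapse = ", "), call. = FALSE)
  }
  parents <- stats::na.omit(c(ped$mother, ped$father))
  missing <- setdiff(parents, ped$id)
  if (length(missing)) {
    stop("pedigree references unknown parent id(s): ",
         paste(unique(missing), collapse = ", "), call. = FALSE)
  }
  # Kahn topological sort; leftover nodes form a cycle
  remaining <- ped
  sorted <- remaining[0, ]
  placed <- character(0)
  repeat {
    ready <- is.na(remaining$mother) | remaining$mother %in% placed
    ready <- ready & (is.na(remaining$father) | remaining$father %in% placed)
    if (!any(ready)) break
    sorted <- dplyr::bind_rows(sorted, remaining[ready, ])
    placed <- c(placed, remaining$id[ready])
    remaining <- remaining[!ready, ]
    if (nrow(remaining) == 0) break
  }
  if (nrow(remaining) > 0) {
    stop("pedigree contains a cycle involving: ",
         paste(remaining$id, collapse = ", "), call. = FALSE)
  }
  sorted
}

#' Write / read tree-level phenotypes as CSV
#'
#' Columns: `genotype`, `environment`, `block`, `row`, `col`, `trait`,
#' `value`. The reader rejects duplicated (environment, row, col) cells
#' within a trait.
#'
#' @param trees phenotype tibble.
#' @param path file path.
#' @export
write_phenotypes <- function(trees, path) {
  readr::write_csv(trees, path)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  trees <- readr::read_csv(path, col_types = readr::cols(
    genotype = readr::col_character(), environment = readr::col_character(),
    block = readr::col_integer(), row = readr::col_integer(),
    col = readr::col_integer(), trait = readr::col_character(),
    value = readr::col_double()))
  dup <- trees |>
    dplyr::count(trait, environment, row, col) |>
    dplyr::filter(n > 1)
  if (nrow(dup) > 0) {
    stop("duplicated field positions: ",
         paste(utils::head(paste(dup$environment, dup$row, dup$col, sep = ":"), 5),
               collapse = ", "), call. = FALSE)
  }
  trees
}

#' Write a stage-results JSON record
#'
#' Schema: `{stage, params, seed, metrics}`; deterministic field order.
#'
#' @param stage stage name.
#' @param params named list echoed verbatim.
#' @param seed integer seed used by the stage.
#' @param metrics named list of numeric results.
#' @param path file path.
#' @export
write_results_json <- function(stage, params, seed, metrics, path) {
  jsonlite::write_json(list(stage = stage, params = params, seed = seed,
                            metrics = metrics),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
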