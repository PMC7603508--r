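#' Pairwise genetic distance between individuals
#'
#' Default is the allele-sharing dissimilarity: mean over markers of
#' `|dosage_a - dosage_b| / 2`, in `[0, 1]`. A Euclidean alternative on
#' dosages is also available.
#'
#' @param panel complete [genotype_panel()].
#' @param metric `"allele-share"` or `"euclidean"`.
#' @return a `dist` object with the metric recorded in
#'   `attr(, "metric")`.
#' @export
gt_distance <- function(panel, metric = c("allele-share", "euclidean")) {
  metric <- match.arg(metric)
  d <- if (metric == "allele-share") {
    stats::dist(panel$dosage, method = "manhattan") / (2 * ncol(panel$dosage))
  } else {
    stats::dist(panel$dosage, method = "euclidean")
  }
  attr(d, "metric") <- metric
  d
}

#' Unrooted neighbor-joining tree
#'
#' Saitou-Nei neighbor joining (via \pkg{ape}); any negative branch
#' length is clamped to zero with its length transferred to the
#' adjacent edge so path lengths are preserved as far as possible.
#'
#' @param d a `dist` or symmetric matrix over >= 3 individuals.
#' @return an \pkg{ape} `phylo` tree (unrooted).
#' @export
nj_tree <- function(d) {
  m <- as.matrix(d)
  if (!isSymmetric(unname(m), tol = 1e-8)) stop("distance matrix must be symmetric",
                                                call. = FALSE)
  if (nrow(m) < 3) stop("need at least 3 individuals", call. = FALSE)
  tr <- ape::nj(stats::as.dist(m))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    len <- tr$edge.length[e]
    parent <- tr$edge[e, 1]
    sib <- setdiff(which(tr$edge[, 1] == parent | tr$edge[, 2] == parent), e)
    if (length(sib)) tr$edge.length[sib[1]] <- tr$edge.length[sib[1]] + len
    tr$edge.length[e] <- 0
  }
  tr
}

#' PCA with supplementary individuals
#'
#' Centers (and optionally scales) markers using the ACTIVE individuals
#' only, computes loadings from the active covariance, and projects the
#' supplementary individuals onto those axes. Constant markers in the
#' active set are dropped with a count. Explained-variance proportions
#' come from the active eigenvalues.
#'
#' @param active [genotype_panel()] used to estimate the axes.
#' @param supplementary optional [genotype_panel()] sharing the marker
#'   map (or a bare numeric matrix over the same markers, e.g. expected
#'   dosages), projected after fitting.
#' @param n_components number of components to keep.
#' @param scale. scale markers to unit variance (default off: marker
#'   variance carries information).
#' @return list of class `pca_sup`: `scores` (tibble with `id`, `set`
#'   ("active"/"supplementary"), `group`, `PC1..PCk`), `loadings`,
#'   `explained` (proportions), `center`, `n_constant_dropped`.
#' @export
pca_supplementary <- function(active, supplementary = NULL, n_components = 10,
                              scale. = FALSE) {
  X <- active$dosage
  sdv <- apply(X, 2, stats::sd)
  const <- sdv == 0
  X <- X[, !const, drop = FALSE]
  pc <- stats::prcomp(X, center = TRUE, scale. = scale.)
  k <- min(n_components, ncol(pc$rotation))
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  sc_act <- pc$x[, seq_len(k), drop = FALSE]
  scores <- tibble::as_tibble(sc_act) |>
    dplyr::mutate(id = rownames(X), set = "active",
                  group = active$info$origin, .before = 1)
  if (!is.null(supplementary)) {
    if (inherits(supplementary, "genotype_panel")) {
      if (!identical(supplementary$map$marker, active$map$marker)) {
        stop("supplementary panel must share the marker map", call. = FALSE)
      }
      S <- supplementary$dosage
      grp <- supplementary$info$origin
    } else {
      S <- as.matrix(supplementary)
      if (ncol(S) != ncol(active$dosage)) {
        stop("supplementary matrix must cover the active markers", call. = FALSE)
      }
      grp <- rep("supplementary", nrow(S))
    }
    S <- S[, !const, drop = FALSE]
    S <- sweep(S, 2, pc$center)
    if (scale.) S <- sweep(S, 2, pc$scale, "/")
    sc_sup <- S %*% pc$rotation[, seq_len(k), drop = FALSE]
    scores <- dplyr::bind_rows(
      scores,
      tibble::as_tibble(sc_sup) |>
        dplyr::mutate(id = rownames(S), set = "supplementary",
                      group = grp, .before = 1))
  }
  structure(list(scores = scores,
                 loadings = pc$rotation[, seq_len(k), drop = FALSE],
                 explained = expl[seq_len(k)], center = pc$center,
                 scaled = scale., n_constant_dropped = sum(const)),
            class = "pca_sup")
}

#' @export
print.pca_sup <- function(x, ...) {
  cat("<pca_sup> ", sum(x$scores$set == "active"), " active + ",
      sum(x$scores$set == "supplementary"), " supplementary individuals\n",
      sep = "")
  cat("  PC1/PC2 explain ",
      sprintf("%.1f%% / %.1f%%", 100 * x$explained[1], 100 * x$explained[2]),
      " of active variance\n", sep = "")
  invisible(x)
}

#' Plot PCA scores with supplementary individuals
#' @param object a `pca_sup` object.
#' @param ... unused.
#' @return a ggplot of PC1 vs PC2.
#' @exportS3Method ggplot2::autoplot
autoplot.pca_sup <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(PC1, PC2, colour = group, shape = set)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$explained[2]))
}
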