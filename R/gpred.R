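#' Fit an RR-BLUP genomic prediction model
#'
#' Ridge-regression BLUP of marker effects: `y = 1 mu + G u + e` with
#' `u ~ N(0, I sigma2_u)`. Variance components are estimated by
#' spectral REML on the equivalent GBLUP kernel `G G'` (one
#' eigendecomposition, Brent search on the log variance ratio); marker
#' effects solve the mixed-model equations. The `dual` method solves the
#' n x n kernel system (preferred when markers >> individuals), the
#' `primal` method the (m+1) mixed-model equations directly.
#'
#' @param G dosage matrix (individuals x markers) or [genotype_panel()].
#' @param y numeric phenotype vector (e.g. LS-means) aligned with rows
#'   of `G`, or a tibble (`genotype`, `lsmean`).
#' @param lambda optional fixed ridge parameter `sigma2_e / sigma2_u`;
#'   default is REML-estimated.
#' @param center center markers by twice the allele frequency (RR-BLUP
#'   convention). Disable when `G` is already coded/centred.
#' @param method `"dual"` or `"primal"`.
#' @return object of class `rrblup_fit` with elements `mu`, `u` (marker
#'   effects), `lambda`, `sigma2_u`, `sigma2_e`, `center` (centering
#'   vector), `fitted`.
#' @export
fit_rrblup <- function(G, y, lambda = NULL, center = TRUE,
                       method = c("dual", "primal")) {
  method <- match.arg(method)
  if (inherits(G, "genotype_panel")) G <- G$dosage
  if (is.data.frame(y)) y <- stats::setNames(y$lsmean, y$genotype)[rownames(G)]
  y <- as.numeric(y)
  n <- nrow(G)
  cvec <- if (center) colMeans(G) else rep(0, ncol(G))
  Gc <- sweep(G, 2, cvec)
  C <- tcrossprod(Gc)
  eg <- eigen(C, symmetric = TRUE)
  S <- pmax(eg$values, 0)
  sigma2 <- c(u = NA_real_, e = NA_real_)
  if (is.null(lambda)) {
    yr <- as.numeric(crossprod(eg$vectors, y))
    Xr <- crossprod(eg$vectors, matrix(1, n, 1))
    lambda <- reml_delta(yr, Xr, S)
    w <- 1 / (S + lambda)
    qrX <- qr(Xr * sqrt(w))
    rss <- sum(qr.resid(qrX, yr * sqrt(w))^2)
    sigma2["u"] <- rss / (n - 1)
    sigma2["e"] <- lambda * sigma2["u"]
  }
  if (method == "dual") {
    V <- C + diag(lambda, n)
    Vi <- solve(V)
    mu <- as.numeric(sum(Vi %*% y) / sum(Vi))
    alpha <- Vi %*% (y - mu)
    u <- as.numeric(crossprod(Gc, alpha))
  } else {
    m <- ncol(Gc)
    A <- rbind(cbind(n, t(colSums(Gc))),
               cbind(colSums(Gc), crossprod(Gc) + diag(lambda, m)))
    b <- c(sum(y), as.numeric(crossprod(Gc, y)))
    sol <- solve(A, b)
    mu <- sol[1]; u <- sol[-1]
  }
  fitted <- as.numeric(mu + Gc %*% u)
  structure(list(mu = mu, u = stats::setNames(u, colnames(G)),
                 lambda = lambda, sigma2_u = unname(sigma2["u"]),
                 sigma2_e = unname(sigma2["e"]), center = cvec,
                 fitted = fitted, method = method),
            class = "rrblup_fit")
}

#' @export
print.rrblup_fit <- function(x, ...) {
  cat("<rrblup_fit> ", length(x$u), " marker effects, lambda = ",
      format(x$lambda, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Predict genomic values for new individuals
#' @param object an `rrblup_fit`.
#' @param newdata dosage matrix or [genotype_panel()] with the same
#'   markers.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.rrblup_fit <- function(object, newdata, ...) {
  if (inherits(newdata, "genotype_panel")) newdata <- newdata$dosage
  as.numeric(object$mu + sweep(newdata, 2, object$center) %*% object$u)
}

#' @exportS3Method generics::tidy
tidy.rrblup_fit <- function(x, ...) {
  tibble::tibble(marker = names(x$u), effect = unname(x$u))
}

#' @exportS3Method generics::glance
glance.rrblup_fit <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, sigma2_u = x$sigma2_u,
                 sigma2_e = x$sigma2_e, n_markers = length(x$u))
}

# Kernel-space CV engine: trains GBLUP on precomputed cross-products so
# repeated folds avoid re-forming G G'. P = G G' (raw dosages),
# rs = G 1 (row sums of G over markers), used to re-centre blocks by the
# training allele frequencies without touching G again.
cv_fold_predict <- function(P, G, y, train, val) {
  cvec <- colMeans(G[train, , drop = FALSE])
  s <- as.numeric(G %*% cvec)            # G c for all individuals
  cc <- sum(cvec^2)
  Ctt <- P[train, train] - outer(s[train], rep(1, length(train))) -
    outer(rep(1, length(train)), s[train]) + cc
  Cvt <- P[val, train] - outer(s[val], rep(1, length(train))) -
    outer(rep(1, length(val)), s[train]) + cc
  eg <- eigen(Ctt, symmetric = TRUE)
  S <- pmax(eg$values, 0)
  yr <- as.numeric(crossprod(eg$vectors, y[train]))
  Xr <- crossprod(eg$vectors, matrix(1, length(train), 1))
  lambda <- reml_delta(yr, Xr, S)
  Vi <- eg$vectors %*% (t(eg$vectors) / (S + lambda))
  mu <- as.numeric(sum(Vi %*% y[train]) / sum(Vi))
  alpha <- Vi %*% (y[train] - mu)
  as.numeric(mu + Cvt %*% alpha)
}

#' Repeated k-fold cross-validation of genomic prediction
#'
#' Per repetition, genotypes are partitioned at random into `folds`
#' groups; each fold is predicted from an RR-BLUP model trained on the
#' remaining genotypes (ridge parameter re-estimated inside every
#' training fold, no leakage). Predictive ability is the Pearson
#' correlation between observed and predicted values in the validation
#' fold, averaged over folds within a repetition (per-fold convention;
#' the pooled correlation over all validation predictions is reported
#' alongside). A repetition whose smallest fold has fewer than 3
#' genotypes is rejected and resampled.
#'
#' @param panel complete [genotype_panel()] (or dosage matrix).
#' @param y phenotype vector or tibble (`genotype`, `lsmean`).
#' @param folds number of folds.
#' @param repetitions number of repetitions.
#' @param seed integer seed.
#' @return object of class `cv_result`: `per_rep` tibble (`rep`,
#'   `ability`, `ability_pooled`), `ability` (grand mean), `folds`,
#'   `repetitions`.
#' @export
cross_validate <- function(panel, y, folds = 5, repetitions = 100, seed = 1) {
  G <- if (inherits(panel, "genotype_panel")) panel$dosage else panel
  if (is.data.frame(y)) y <- stats::setNames(y$lsmean, y$genotype)[rownames(G)]
  y <- as.numeric(y)
  n <- nrow(G)
  if (n < folds) stop("fewer genotypes than folds", call. = FALSE)
  set.seed(seed)
  P <- tcrossprod(G)
  per_rep <- purrr::map_dfr(seq_len(repetitions), function(rep_i) {
    repeat {
      fold_id <- sample(rep(seq_len(folds), length.out = n))
      if (min(table(fold_id)) >= 3) break
      message("cross_validate: resampled a repetition with a fold < 3 genotypes")
    }
    preds <- numeric(n)
    r_fold <- numeric(folds)
    for (f in seq_len(folds)) {
      val <- which(fold_id == f); train <- which(fold_id != f)
      preds[val] <- cv_fold_predict(P, G, y, train, val)
      r_fold[f] <- stats::cor(y[val], preds[val])
    }
    tibble::tibble(rep = rep_i, ability = mean(r_fold),
                   ability_pooled = stats::cor(y, preds))
  })
  structure(list(per_rep = per_rep, ability = mean(per_rep$ability),
                 ability_pooled = mean(per_rep$ability_pooled),
                 folds = folds, repetitions = repetitions, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> ", x$repetitions, " x ", x$folds, "-fold CV\n", sep = "")
  cat(sprintf("  mean predictive ability (per-fold) = %.3f, pooled = %.3f\n",
              x$ability, x$ability_pooled))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cv_result <- function(x, ...) x$per_rep

#' @exportS3Method generics::glance
glance.cv_result <- function(x, ...) {
  tibble::tibble(ability = x$ability, ability_pooled = x$ability_pooled,
                 folds = x$folds, repetitions = x$repetitions)
}

#' Plot per-repetition predictive abilities
#' @param object a `cv_result`.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.cv_result <- function(object, ...) {
  ggplot2::ggplot(object$per_rep, ggplot2::aes(x = "", y = ability)) +
    ggplot2::geom_boxplot(width = 0.3) +
    ggplot2::geom_jitter(width = 0.05, alpha = 0.4) +
    ggplot2::labs(x = NULL, y = "predictive ability (Pearson r)")
}
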