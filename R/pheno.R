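#' Spatial adjustment of tree-level phenotypes within one environment
#'
#' Fits, per environment and trait, the mixed model
#' `y = f(row, col) + Z_g c_g + Z_r c_r + Z_c c_c + e` with a
#' tensor-product cubic P-spline surface `f` (second-order difference
#' penalty) and independent random genotype, row and column effects,
#' all selected by REML (via \pkg{mgcv}). The adjusted value of a tree
#' is the predicted genotype value (intercept + genotype effect; smooth
#' surface and row/column effects excluded) plus that tree's residual.
#' A layout with a single row (or column) reduces the surface to a 1D
#' smooth with a warning.
#'
#' @param trees phenotype tibble (`genotype`, `environment`, `block`,
#'   `row`, `col`, `trait`, `value`) restricted to one environment and
#'   one trait (or pass `env`/`trait` to filter).
#' @param env,trait optional filters applied to `trees`.
#' @param knot_spacing approximate rows/columns per spline knot.
#' @return list of class `spatial_fit`: `fit` (the gam), `adjusted`
#'   (the input tibble with columns `value` (adjusted) and `raw`),
#'   `surface` (tibble `row`, `col`, `surface`), `effective_dimensions`
#'   (tibble `term`, `edf`), `env`, `trait`.
#' @export
spatial_adjust <- function(trees, env = NULL, trait = NULL, knot_spacing = 4) {
  if (!is.null(env)) trees <- trees[trees$environment == env, ]
  if (!is.null(trait)) trees <- trees[trees$trait == trait, ]
  if (length(unique(trees$environment)) != 1 || length(unique(trees$trait)) != 1) {
    stop("spatial_adjust works on one environment and one trait at a time",
         call. = FALSE)
  }
  dat <- data.frame(value = trees$value, row = trees$row, col = trees$col,
                    genotype = factor(trees$genotype),
                    row_f = factor(trees$row), col_f = factor(trees$col))
  nr <- length(unique(dat$row)); nc <- length(unique(dat$col))
  kr <- max(4, min(ceiling(nr / knot_spacing) + 2, nr - 1))
  kc <- max(4, min(ceiling(nc / knot_spacing) + 2, nc - 1))
  if (nr < 3 || nc < 3) {
    warning("layout is effectively one-dimensional; fitting a 1D smooth")
    dim_var <- if (nr >= 3) "row" else "col"
    k1 <- if (nr >= 3) kr else kc
    form <- stats::as.formula(paste0(
      "value ~ s(", dim_var, ", bs='ps', k=", k1, ", m=c(2,2)) +",
      "s(genotype, bs='re') + s(row_f, bs='re') + s(col_f, bs='re')"))
    smooth_term <- paste0("s(", dim_var, ")")
  } else {
    form <- stats::as.formula(paste0(
      "value ~ te(row, col, bs='ps', k=c(", kr, ",", kc, "), m=list(c(2,2),c(2,2))) +",
      "s(genotype, bs='re') + s(row_f, bs='re') + s(col_f, bs='re')"))
    smooth_term <- "te(row,col)"
  }
  fit <- mgcv::bam(form, data = dat, method = "fREML", discrete = TRUE,
                   nthreads = 1)
  excl <- c(smooth_term, "s(row_f)", "s(col_f)")
  pred_geno <- as.numeric(stats::predict(fit, newdata = dat, exclude = excl,
                                         discrete = FALSE))
  adjusted <- pred_geno + stats::residuals(fit)
  out <- trees
  out$raw <- trees$value
  out$value <- adjusted
  cells <- unique(dat[, c("row", "col")])
  term_mat <- stats::predict(fit,
                             newdata = data.frame(row = cells$row, col = cells$col,
                                                  genotype = dat$genotype[1],
                                                  row_f = dat$row_f[1],
                                                  col_f = dat$col_f[1]),
                             type = "terms", discrete = FALSE)
  sterm <- grep("^(te|s)\\((row|col)", colnames(term_mat), value = TRUE)[1]
  surface <- tibble::tibble(row = cells$row, col = cells$col,
                            surface = as.numeric(term_mat[, sterm]))
  ed <- summary(fit)$s.table
  eff <- tibble::tibble(term = rownames(ed), edf = unname(ed[, "edf"]))
  structure(list(fit = fit, adjusted = tibble::as_tibble(out), surface = surface,
                 effective_dimensions = eff,
                 env = trees$environment[1], trait = trees$trait[1]),
            class = "spatial_fit")
}

#' Spatially adjust all environments of a trial
#'
#' @param trees full phenotype tibble.
#' @param ... passed to [spatial_adjust()].
#' @return list with `adjusted` (tibble over all environments/traits)
#'   and `fits` (list of `spatial_fit`).
#' @export
spatial_adjust_all <- function(trees, ...) {
  combos <- dplyr::distinct(trees, environment, trait)
  fits <- purrr::pmap(combos, function(environment, trait) {
    spatial_adjust(trees, env = environment, trait = trait, ...)
  })
  list(adjusted = dplyr::bind_rows(purrr::map(fits, "adjusted")), fits = fits)
}

#' Plot a fitted spatial surface
#' @param object a `spatial_fit`.
#' @param ... unused.
#' @return a ggplot heat map of the fitted surface.
#' @exportS3Method ggplot2::autoplot
autoplot.spatial_fit <- function(object, ...) {
  ggplot2::ggplot(object$surface, ggplot2::aes(col, row, fill = surface)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(title = paste("fitted spatial surface:", object$env))
}

lmer_varcomp <- function(fit) {
  vc <- as.data.frame(lme4::VarCorr(fit))
  stats::setNames(vc$vcov, ifelse(vc$grp == "Residual", "residual", vc$grp))
}

#' Individual-location clonal-mean heritability
#'
#' For each environment (and trait) fits the one-way random-effects
#' model `y_ik = mu + g_i + e_ik` by REML and reports
#' `H2 = sigma2_g / (sigma2_g + sigma2_e / n_bar_r)`, with `n_bar_r`
#' the mean number of replicates per genotype (arithmetic by default,
#' harmonic behind a flag).
#'
#' @param trees phenotype tibble (raw or spatially adjusted).
#' @param harmonic use the harmonic mean of replicate counts.
#' @return tibble: `environment`, `trait`, `sigma2_g`, `sigma2_e`,
#'   `n_bar_r`, `sigma2_p`, `H2`, `n_genotypes`.
#' @export
h2_individual <- function(trees, harmonic = FALSE) {
  trees |>
    dplyr::group_by(environment, trait) |>
    dplyr::group_modify(function(d, key) {
      reps <- table(d$genotype)
      if (max(reps) < 2) {
        stop("all genotypes are singletons in ", key$environment,
             "; genotypic variance unidentifiable", call. = FALSE)
      }
      n_bar <- if (harmonic) 1 / mean(1 / reps) else mean(reps)
      fit <- lme4::lmer(value ~ 1 + (1 | genotype), data = d, REML = TRUE,
                        control = lme4::lmerControl(check.conv.singular = "ignore"))
      vc <- lmer_varcomp(fit)
      s2g <- unname(vc["genotype"]); s2e <- unname(vc["residual"])
      s2p <- s2g + s2e / n_bar
      tibble::tibble(sigma2_g = s2g, sigma2_e = s2e, n_bar_r = n_bar,
                     sigma2_p = s2p, H2 = s2g / s2p,
                     n_genotypes = length(reps))
    }) |>
    dplyr::ungroup()
}

#' Drop trials with heritability below a threshold
#'
#' @param h2_table output of [h2_individual()].
#' @param threshold minimum H2 for a trial to be retained.
#' @return tibble of retained (`environment`, `trait`) rows; excluded
#'   trials are reported via `message()`. Errors if nothing survives.
#' @export
exclude_low_h2 <- function(h2_table, threshold = 0.1) {
  drop <- h2_table$H2 < threshold
  if (all(drop)) stop("all environments fall below the H2 threshold", call. = FALSE)
  if (any(drop)) {
    message("excluding low-H2 trial(s): ",
            paste(h2_table$environment[drop], "(", h2_table$trait[drop], ")",
                  collapse = ", "))
  }
  h2_table[!drop, c("environment", "trait")]
}

#' Multi-environment variance decomposition and heritability
#'
#' Fits `y_ijk = mu + g_i + l_j + gl_ij + e_ijk` by REML
#' (fixed environment `l_j`, random genotype and genotype-by-environment)
#' and reports: the fraction of phenotypic variation of the fixed
#' environment effect (variance of the fitted values with all random
#' effects set to zero over the total), random-effect variance fractions,
#' 95% profile-likelihood confidence intervals for the random-effect
#' variances, and the multi-location clonal-mean heritability
#' `H2 = sigma2_g / (sigma2_g + sigma2_gl/n_l + sigma2_e/(n_l n_bar_r))`.
#'
#' @param trees spatially adjusted phenotype tibble restricted to one
#'   trait and the retained environments.
#' @param ci compute profile-likelihood CIs (somewhat slow).
#' @return object of class `multienv_fit`.
#' @export
fit_multienv <- function(trees, ci = TRUE) {
  stopifnot(length(unique(trees$trait)) == 1)
  n_l <- length(unique(trees$environment))
  if (n_l < 2) stop("need at least 2 environments", call. = FALSE)
  d <- data.frame(value = trees$value, genotype = factor(trees$genotype),
                  environment = factor(trees$environment))
  reps <- dplyr::count(tibble::as_tibble(d), genotype, environment)
  n_bar <- mean(reps$n)
  fit <- lme4::lmer(value ~ environment + (1 | genotype) +
                      (1 | genotype:environment),
                    data = d, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  vc <- lmer_varcomp(fit)
  s2g <- unname(vc["genotype"])
  s2gl <- unname(vc["genotype:environment"])
  s2e <- unname(vc["residual"])
  fixed_pred <- as.numeric(lme4::getME(fit, "X") %*% lme4::fixef(fit))
  v_fixed <- stats::var(fixed_pred)
  total <- v_fixed + s2g + s2gl + s2e
  ci_tab <- tibble::tibble(component = c("genotype", "gxe", "residual"),
                           ci_lower = ifelse(c(s2g, s2gl, s2e) < 1e-8, 0, NA_real_),
                           ci_upper = NA_real_)
  if (ci) {
    prof <- tryCatch(
      suppressWarnings(stats::confint(fit, parm = "theta_", method = "profile",
                                      level = 0.95, quiet = TRUE)),
      error = function(e) NULL)
    if (!is.null(prof)) {
      # rows are SD-scale: .sig01 (genotype:environment), .sig02 (genotype),
      # .sigma (residual) -- map by matching VarCorr order
      vc_names <- as.data.frame(lme4::VarCorr(fit))$grp
      sd_ci <- prof^2
      lab <- c("genotype:environment" = "gxe", "genotype" = "genotype",
               "Residual" = "residual")
      rn <- c(lab[vc_names])
      ci_tab <- tibble::tibble(component = rn, ci_lower = sd_ci[, 1],
                               ci_upper = sd_ci[, 2])
    }
  }
  varcomp <- tibble::tibble(
    component = c("environment (fixed)", "genotype", "gxe", "residual"),
    variance = c(v_fixed, s2g, s2gl, s2e),
    fraction = c(v_fixed, s2g, s2gl, s2e) / total
  ) |>
    dplyr::left_join(ci_tab, by = "component")
  s2p <- s2g + s2gl / n_l + s2e / (n_l * n_bar)
  structure(list(fit = fit, varcomp = varcomp,
                 heritability = tibble::tibble(
                   sigma2_g = s2g, sigma2_gl = s2gl, sigma2_e = s2e,
                   n_l = n_l, n_bar_r = n_bar, sigma2_p = s2p,
                   H2 = s2g / s2p),
                 trait = trees$trait[1]),
            class = "multienv_fit")
}

#' @export
print.multienv_fit <- function(x, ...) {
  cat("<multienv_fit> trait:", x$trait, "\n")
  print(x$varcomp)
  cat(sprintf("  multi-location H2 = %.3f (n_l = %d, n_bar_r = %.2f)\n",
              x$heritability$H2, x$heritability$n_l, x$heritability$n_bar_r))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.multienv_fit <- function(x, ...) x$varcomp

#' @exportS3Method generics::glance
glance.multienv_fit <- function(x, ...) x$heritability

check_connected <- function(d) {
  # union-find over genotype/environment incidence
  nodes <- c(paste0("g:", unique(d$genotype)), paste0("e:", unique(d$environment)))
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (i in seq_len(nrow(d))) {
    a <- find(paste0("g:", d$genotype[i])); b <- find(paste0("e:", d$environment[i]))
    if (a != b) parent[[a]] <- b
  }
  roots <- vapply(nodes, find, character(1))
  split(sub("^[ge]:", "", nodes), roots)
}

#' Least-square means of genotypes across environments
#'
#' Fits the additive two-way fixed-effects model
#' `y_ijk = mu + g_i + l_j + e_ijk` by OLS and reports, per genotype,
#' the mean of `mu + g_i + l_j` over ALL retained environments --
#' identical to the normal-equations LS-means.
#'
#' @param trees adjusted phenotype tibble (one trait), already
#'   restricted to retained environments.
#' @param retained optional tibble/vector of environments to keep.
#' @return tibble `genotype`, `trait`, `lsmean`.
#' @export
ls_means <- function(trees, retained = NULL) {
  stopifnot(length(unique(trees$trait)) == 1)
  if (!is.null(retained)) {
    envs <- if (is.data.frame(retained)) retained$environment else retained
    trees <- trees[trees$environment %in% envs, ]
  }
  d <- data.frame(value = trees$value, genotype = factor(trees$genotype),
                  environment = factor(trees$environment))
  comp <- check_connected(d)
  if (length(comp) > 1) {
    stop("disconnected genotype x environment design; components: ",
         paste(vapply(comp, function(x) paste(utils::head(x, 3), collapse = "+"),
                      character(1)), collapse = " | "), call. = FALSE)
  }
  form <- if (nlevels(d$environment) > 1) value ~ genotype + environment
          else value ~ genotype
  fit <- stats::lm(form, data = d)
  grid <- expand.grid(genotype = levels(d$genotype),
                      environment = levels(d$environment))
  grid$pred <- stats::predict(fit, newdata = grid)
  out <- grid |>
    dplyr::group_by(genotype) |>
    dplyr::summarise(lsmean = mean(pred), .groups = "drop") |>
    dplyr::mutate(genotype = as.character(genotype), trait = trees$trait[1],
                  .before = 2)
  out[, c("genotype", "trait", "lsmean")]
}
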