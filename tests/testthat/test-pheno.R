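test_that("spatial adjustment is a no-op without surface, row/col or noise", {
  set.seed(8)
  ng <- 60
  g <- rnorm(ng, 250, 5)
  layout <- expand.grid(row = 1:10, col = 1:12)[1:(2 * ng), ]
  trees <- tibble::tibble(
    genotype = rep(paste0("g", 1:ng), 2)[sample(2 * ng)],
    environment = "e1", block = rep(1:2, each = ng),
    row = layout$row, col = layout$col, trait = "t")
  trees$value <- g[match(trees$genotype, paste0("g", 1:ng))]
  sf <- suppressWarnings(spatial_adjust(trees))
  expect_lt(max(abs(sf$adjusted$value - sf$adjusted$raw)), 1e-6)
  expect_true(all(sf$effective_dimensions$edf >= 0))
})

test_that("a planted smooth surface is recovered and H2 does not drop", {
  fx <- pop_small()
  sp <- trait_spec(n_causal = 60, var_genotype = 0.5, var_environment = 0.05,
                   var_gxe = 0.05, var_spatial = 0.3, var_residual = 0.1)
  ph <- simulate_phenotypes(fx$pop$panel, sp, n_environments = 2, blocks = 2,
                            field_rows = 10, seed = 11)
  adj <- spatial_adjust_all(ph$trees)
  for (i in seq_along(adj$fits)) {
    f <- adj$fits[[i]]
    tru <- ph$truth$spatial[ph$truth$spatial$environment == f$env, ]
    j <- merge(tru, f$surface, by = c("row", "col"))
    expect_gt(stats::cor(j$surface.x, j$surface.y), 0.9)
  }
  h2_raw <- h2_individual(ph$trees)
  h2_adj <- h2_individual(adj$adjusted)
  expect_true(all(h2_adj$H2 >= h2_raw$H2 - 1e-10))
})

test_that("one-way REML equals closed-form balanced ANOVA estimators", {
  trees <- balanced_trees(ng = 200, reps = 4, s2g = 2, s2e = 2, seed = 5)
  h <- h2_individual(trees)
  av <- stats::anova(stats::lm(value ~ genotype, trees))
  msb <- av$`Mean Sq`[1]; msw <- av$`Mean Sq`[2]
  expect_equal(h$sigma2_g, (msb - msw) / 4, tolerance = 1e-6)
  expect_equal(h$sigma2_e, msw, tolerance = 1e-6)
  # phenotypic variance reconstructs exactly from its components
  expect_equal(h$sigma2_p, h$sigma2_g + h$sigma2_e / h$n_bar_r)
  # the heritability identity at stated component values
  expect_equal(3 / (3 + 1 / 2), 0.857, tolerance = 5e-4)
  # zero residual: identical replicates give H2 = 1
  pure <- trees
  pure$value <- rep(stats::rnorm(200), each = 4)
  hp <- suppressWarnings(h2_individual(pure))  # boundary fit: sigma2_e -> 0
  expect_gt(hp$H2, 1 - 1e-6)
  # all-singleton genotypes are rejected
  expect_error(h2_individual(trees[!duplicated(trees$genotype), ]),
               "singleton")
})

test_that("low-heritability trials are excluded by the 0.1 rule", {
  h2t <- tibble::tibble(environment = c("e1", "e2", "e3"), trait = "t",
                        H2 = c(0.05, 0.6, 0.8))
  expect_message(kept <- exclude_low_h2(h2t), "e1")
  expect_equal(kept$environment, c("e2", "e3"))
  all_good <- dplyr::mutate(h2t, H2 = c(0.2, 0.6, 0.8))
  expect_equal(exclude_low_h2(all_good)$environment, c("e1", "e2", "e3"))
  none <- dplyr::mutate(h2t, H2 = 0.01)
  expect_error(exclude_low_h2(none), "all environments")
  # a planted pure-noise environment is the one excluded
  fx <- pop_small()
  sp <- trait_spec(n_causal = 50, var_genotype = 0.6, var_environment = 0.05,
                   var_gxe = 0.05, var_spatial = 0, var_residual = 0.3)
  ph <- simulate_phenotypes(fx$pop$panel, sp, n_environments = 3, blocks = 2,
                            field_rows = 10, seed = 13)
  noisy <- ph$trees
  bad <- noisy$environment == "env_2"
  set.seed(1)
  noisy$value[bad] <- mean(noisy$value) + stats::rnorm(sum(bad), 0, 10)
  h2n <- h2_individual(noisy)
  kept2 <- exclude_low_h2(h2n)
  expect_setequal(kept2$environment, c("env_1", "env_3"))
})

test_that("multi-environment REML reconstructs variances and flags boundaries", {
  fx <- pop_small()
  sp <- trait_spec(n_causal = 60, var_genotype = 0.6, var_environment = 0.1,
                   var_gxe = 0.1, var_spatial = 0, var_residual = 0.2)
  ph <- simulate_phenotypes(fx$pop$panel, sp, n_environments = 3, blocks = 2,
                            field_rows = 10, seed = 17)
  me <- fit_multienv(ph$trees, ci = FALSE)
  hh <- me$heritability
  # Eq-form reconstruction is exact
  expect_equal(hh$sigma2_p,
               hh$sigma2_g + hh$sigma2_gl / hh$n_l +
                 hh$sigma2_e / (hh$n_l * hh$n_bar_r))
  # the same identity at stated component values
  expect_equal(4 / (4 + 2 / 5 + 2 / (5 * 2)), 0.870, tolerance = 5e-4)
  expect_true(all(me$varcomp$fraction >= 0) && sum(me$varcomp$fraction) <= 1 + 1e-8)
  # zero planted GxE: its CI lower bound sits at zero
  sp0 <- trait_spec(n_causal = 60, var_genotype = 0.6, var_environment = 0.1,
                    var_gxe = 0, var_spatial = 0, var_residual = 0.3)
  ph0 <- simulate_phenotypes(fx$pop$panel, sp0, n_environments = 3, blocks = 2,
                             field_rows = 10, seed = 19)
  me0 <- fit_multienv(ph0$trees, ci = TRUE)
  gxe_row <- me0$varcomp[me0$varcomp$component == "gxe", ]
  expect_lt(gxe_row$ci_lower, 1e-4)
  expect_error(fit_multienv(ph$trees[ph$trees$environment == "env_1", ]),
               "2 environments")
})

test_that("LS-means equal the normal-equations solution", {
  # balanced case: cell-mean average
  bal <- tibble::tibble(
    genotype = rep(c("A", "B"), each = 2),
    environment = rep(c("E1", "E2"), 2), block = 1, row = 1:4, col = 1,
    trait = "t", value = c(10, 20, 12, 26))
  lm_b <- ls_means(bal)
  expect_equal(lm_b$lsmean[lm_b$genotype == "A"], 15)
  expect_equal(lm_b$lsmean[lm_b$genotype == "B"], 19)
  # single environment: genotype means
  one <- bal[bal$environment == "E1", ]
  lm_o <- ls_means(one)
  expect_equal(lm_o$lsmean, c(10, 12))
  # unbalanced case against a direct normal-equations solve
  unb <- tibble::tibble(
    genotype = c("A", "A", "B", "B", "C", "C", "C"),
    environment = c("E1", "E1", "E1", "E2", "E1", "E2", "E2"),
    block = 1, row = 1:7, col = 1, trait = "t",
    value = c(10, 11, 14, 20, 9, 16, 17))
  got <- ls_means(unb)
  X <- stats::model.matrix(~genotype + environment, unb)
  beta <- solve(crossprod(X), crossprod(X, unb$value))
  grid <- expand.grid(genotype = c("A", "B", "C"), environment = c("E1", "E2"))
  Xg <- stats::model.matrix(~genotype + environment, grid)
  ref <- tapply(Xg %*% beta, grid$genotype, mean)
  expect_equal(got$lsmean, as.numeric(ref[got$genotype]), tolerance = 1e-10)
  # reparameterization invariance: shift one environment, compensate its effect
  shifted <- unb
  shifted$value[shifted$environment == "E2"] <- shifted$value[shifted$environment == "E2"] + 7
  got_shift <- ls_means(shifted)
  expect_equal(got_shift$lsmean - got$lsmean, rep(7 / 2, 3), tolerance = 1e-10)
  # disconnected designs are refused
  disc <- tibble::tibble(
    genotype = c("A", "A", "B", "B"), environment = c("E1", "E1", "E2", "E2"),
    block = 1, row = 1:4, col = 1, trait = "t", value = 1:4)
  expect_error(ls_means(disc), "disconnected")
})
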