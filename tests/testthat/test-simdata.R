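test_that("config invariants are enforced", {
  expect_error(sim_config(origin_counts = c(A = 10)), "origin_counts")
  expect_error(sim_config(n_snps_scaffold = 100, n_snps_full = 50), "scaffold")
  expect_error(sim_config(maf_min = 0.6), "maf_min")
  expect_error(trait_spec(var_genotype = 0.9), "sum to 1")
})

test_that("founder LD decay responds to the copy-length parameter", {
  base <- list(n_accessions = 60, origin_counts = c(A = 60), n_chromosomes = 2,
               n_snps_full = 400, n_snps_scaffold = 100)
  # independence limit: negligible copy length
  cfg0 <- do.call(sim_config, c(base, list(ld_decay_bp = 1e-6, seed = 1)))
  p0 <- simulate_founders(cfg0)$panel
  pr0 <- ld_sample_pairs(p0, fraction = 0.5, seed = 1)
  expect_lt(mean(pr0$r2[pr0$dist_bp <= 1000]), 0.05)
  # full-linkage limit: copy length far beyond the chromosome
  cfg1 <- do.call(sim_config, c(base, list(ld_decay_bp = 1e12, seed = 1)))
  p1 <- simulate_founders(cfg1)$panel
  d1 <- p1$dosage
  adj <- vapply(seq_len(ncol(d1) - 1), function(j) {
    if (p1$map$chrom[j] != p1$map$chrom[j + 1]) return(NA_real_)
    suppressWarnings(stats::cor(d1[, j], d1[, j + 1])^2)
  }, numeric(1))
  expect_gt(mean(adj, na.rm = TRUE), 0.99)
})

test_that("windowed mean r2 decreases with distance on the desk-scale panel", {
  cfg <- sim_config(n_accessions = 600,
                    origin_counts = c(NEE = 60, WCE = 300, SE = 60, U = 180),
                    n_snps_full = 20000, n_snps_scaffold = 1000, seed = 1)
  pan <- simulate_founders(cfg)$panel
  expect_true(all(panel_maf(pan) >= cfg$maf_min))
  pairs <- ld_sample_pairs(pan, fraction = 0.1, seed = 1)
  bins <- c(100, 1000, 5000, 100000)
  wm <- ld_decay(pairs, ref_distances = bins, window_bp = 200)$window_means
  expect_true(all(diff(wm$mean_r2) < 0))
  .fix$desk_panel <- pan   # reused by the LD threshold test
})

test_that("meiosis respects the crossover model", {
  fx <- pop_small()
  haps <- fx$pop$haplotypes
  acc <- rownames(haps$H1)[1:2]
  # no crossovers: gametes are intact parental haplotypes
  off0 <- simulate_cross(haps, acc[1], acc[2], 5, recomb_rate = 0)
  for (k in 1:5) {
    for (ch in unique(haps$map$chrom)) {
      idx <- haps$map$chrom == ch
      expect_true(identical(off0$H1[k, idx], haps$H1[acc[1], idx]) ||
                    identical(off0$H1[k, idx], haps$H2[acc[1], idx]))
    }
  }
  # selfing a fully homozygous parent reproduces it exactly
  hom <- haps
  hom$H2 <- hom$H1
  selfed <- simulate_cross(hom, acc[1], acc[1], 3, recomb_rate = 2)
  for (k in 1:3) {
    expect_equal(unname(selfed$H1[k, ] + selfed$H2[k, ]),
                 unname(2 * hom$H1[acc[1], ]))
  }
  # observed crossover count matches Poisson(1.5) within 3 SE
  set.seed(7)
  n_off <- 200
  off <- simulate_cross(haps, acc[1], acc[2], n_off, recomb_rate = 1.5)
  count_switches <- function(gamete, h1, h2, map) {
    tot <- 0
    for (ch in unique(map$chrom)) {
      idx <- which(map$chrom == ch)
      inf <- idx[h1[idx] != h2[idx]]
      if (length(inf) < 2) next
      src <- ifelse(gamete[inf] == h1[inf], 1L, 2L)
      tot <- tot + sum(diff(src) != 0)
    }
    tot
  }
  nchrom <- length(unique(haps$map$chrom))
  counts <- vapply(seq_len(n_off), function(k) {
    count_switches(off$H1[k, ], haps$H1[acc[1], ], haps$H2[acc[1], ], haps$map)
  }, numeric(1))
  mean_per_chrom <- mean(counts) / nchrom
  se <- sqrt(1.5 / (n_off * nchrom))
  expect_lt(abs(mean_per_chrom - 1.5), 3 * se)
})

test_that("simulated trios are Mendelian-consistent", {
  fx <- pop_small()
  pop <- fx$pop
  dos <- pop$panel$dosage
  prog <- pop$pedigree[!is.na(pop$pedigree$mother), ]
  for (i in seq_len(nrow(prog))) {
    o <- dos[prog$id[i], ]; m <- dos[prog$mother[i], ]; f <- dos[prog$father[i], ]
    expect_equal(sum(o == 2 & (m == 0 | f == 0)), 0)
    expect_equal(sum(o == 0 & (m == 2 | f == 2)), 0)
  }
})

test_that("the same seed reproduces the population exactly", {
  cfg <- sim_config(n_accessions = 30, origin_counts = c(A = 30), n_families = 3,
                    n_progeny = 12, n_chromosomes = 2, n_snps_full = 300,
                    n_snps_scaffold = 50, seed = 9)
  p1 <- simulate_population(cfg)
  p2 <- simulate_population(cfg)
  expect_identical(p1$panel$dosage, p2$panel$dosage)
  expect_identical(p1$pedigree, p2$pedigree)
  ph1 <- simulate_phenotypes(p1$panel, trait_spec(n_causal = 50),
                             n_environments = 2, seed = 4)
  ph2 <- simulate_phenotypes(p2$panel, trait_spec(n_causal = 50),
                             n_environments = 2, seed = 4)
  expect_identical(ph1$trees, ph2$trees)
})

test_that("scaffold masking is even, seeded and reversible", {
  fx <- pop_small()
  pan <- fx$pop$panel
  # identity masking
  full <- mask_to_scaffold(pan, ncol(pan$dosage))
  expect_identical(full$index, seq_len(ncol(pan$dosage)))
  # per-chromosome allocation: floor(share) or floor(share)+1
  mk <- mask_to_scaffold(pan, 200, seed = 3)
  expect_length(mk$index, 200)
  got <- table(pan$map$chrom[mk$index])
  share <- 200 * table(pan$map$chrom) / ncol(pan$dosage)
  expect_true(all(abs(as.numeric(got) - as.numeric(share)) <= 1))
  # round trip through the index map is exact
  expect_identical(mk$scaffold$dosage,
                   pan$dosage[, mk$index])
  # missing fraction after re-expansion
  expect_equal(fraction_imputed(1000, 20000), 95)
})

test_that("phenotype variance fractions behave at the limits", {
  fx <- pop_small()
  pan <- fx$pop$panel
  # pure noise: estimated H2 near zero
  sp0 <- trait_spec(n_causal = 50, var_genotype = 0, var_environment = 0,
                    var_gxe = 0, var_spatial = 0, var_residual = 1)
  ph0 <- simulate_phenotypes(pan, sp0, n_environments = 2, blocks = 2,
                             field_rows = 10, seed = 2)
  h0 <- h2_individual(ph0$trees)
  expect_true(all(h0$H2 < 0.15))
  # pure genotype: replicate trees identical, H2 = 1
  sp1 <- trait_spec(n_causal = 50, var_genotype = 1, var_environment = 0,
                    var_gxe = 0, var_spatial = 0, var_residual = 0)
  ph1 <- simulate_phenotypes(pan, sp1, n_environments = 2, blocks = 2,
                             field_rows = 10, seed = 2)
  spread <- ph1$trees |>
    dplyr::group_by(genotype) |>
    dplyr::summarise(d = max(value) - min(value))
  expect_true(all(spread$d < 1e-9))
  h1 <- suppressWarnings(h2_individual(ph1$trees))  # boundary fit
  expect_true(all(h1$H2 > 1 - 1e-6))
  # realized fractions are stored and renormalised
  expect_equal(sum(ph0$truth$realized_fractions), 1)
})
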