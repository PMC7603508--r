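two_chrom_haps <- function(H1, H2, ids) {
  m <- ncol(H1)
  map <- tibble::tibble(marker = paste0("m", seq_len(m)),
                        chrom = rep(c("1", "2"), each = m / 2),
                        pos = rep(seq_len(m / 2) * 1000L, 2))
  rownames(H1) <- rownames(H2) <- ids
  structure(list(H1 = H1, H2 = H2, map = map,
                 founder = stats::setNames(rep(TRUE, length(ids)), ids)),
            class = "haplotype_set")
}

test_that("unambiguous transmission is imputed exactly", {
  m <- 40
  # mother heterozygous everywhere (informative), father homozygous ref
  H1 <- rbind(rep(0L, m), rep(0L, m))
  H2 <- rbind(rep(1L, m), rep(0L, m))
  haps <- two_chrom_haps(H1, H2, c("mo", "fa"))
  off <- simulate_cross(haps, "mo", "fa", 6, recomb_rate = 0)
  truth <- off$H1 + off$H2
  scaffold_idx <- c(5L, 15L, 25L, 35L)   # >=1 informative anchor per chromosome
  res <- impute_family(haps, "mo", "fa", truth[, scaffold_idx, drop = FALSE],
                       scaffold_idx)
  expect_equal(unname(res$imputed), unname(truth))
  acc <- imputation_accuracy(res$imputed, truth)
  expect_equal(acc$acc_individuals, 1)
})

test_that("fully uninformative parents give expected dosage 1 and flagged accuracy", {
  m <- 20
  H1 <- rbind(rep(0L, m), rep(0L, m))
  H2 <- rbind(rep(1L, m), rep(1L, m))   # both parents het at every marker
  haps <- two_chrom_haps(H1, H2, c("mo", "fa"))
  scaffold_idx <- c(5L, 15L)
  obs <- matrix(1, 3, 2, dimnames = list(paste0("o", 1:3), NULL))
  res <- impute_family(haps, "mo", "fa", obs, scaffold_idx)
  expect_true(all(res$imputed == 1))
  truth <- matrix(rep(c(0L, 1L, 2L), m)[seq_len(3 * m)], 3, m)
  acc <- imputation_accuracy(res$imputed, truth)
  # constant imputed rows/columns: undefined correlations are counted, not zeroed
  expect_equal(acc$n_undefined_markers, m)
  expect_equal(acc$n_undefined_individuals, 3)
  expect_true(is.na(acc$acc_markers))
})

test_that("Mendelian-inconsistent scaffold cells are flagged and excluded", {
  m <- 20
  H1 <- rbind(rep(0L, m), rep(0L, m))
  H2 <- rbind(rep(1L, m), rep(0L, m))
  haps <- two_chrom_haps(H1, H2, c("mo", "fa"))
  obs <- matrix(c(2, 1), 1, 2, dimnames = list("o1", NULL))  # dosage 2 impossible
  res <- impute_family(haps, "mo", "fa", obs, c(5L, 15L))
  expect_equal(res$flagged$marker, "m5")
  expect_true(all(res$imputed >= 0 & res$imputed <= 2))
})

test_that("accuracy metrics match hand-computed correlations", {
  truth <- rbind(c(0, 1, 2, 0), c(2, 1, 0, 2))
  # identical: both metrics 1
  acc1 <- imputation_accuracy(truth, truth)
  expect_equal(acc1$acc_individuals, 1)
  expect_equal(acc1$acc_markers, 1)
  # complement: both -1
  acc2 <- imputation_accuracy(2 - truth, truth)
  expect_equal(acc2$acc_individuals, -1)
  expect_equal(acc2$acc_markers, -1)
  # single-row hand Pearson
  acc3 <- imputation_accuracy(rbind(c(0, 1, 1, 0)), rbind(c(0, 1, 2, 0)))
  expect_equal(acc3$acc_individuals, 1.5 / sqrt(2.75 * 1), tolerance = 1e-12)
  expect_equal(round(acc3$acc_individuals, 3), 0.905)
  expect_error(imputation_accuracy(truth, truth[, 1:2]), "shape")
})

test_that("fraction imputed follows the percentage identity", {
  expect_equal(round(fraction_imputed(7060, 303239), 1), 97.7)
  expect_equal(fraction_imputed(500, 500), 0)
  expect_equal(fraction_imputed(1000, 20000), 95)
  expect_error(fraction_imputed(10, 5))
})

test_that("simulated-family accuracy is high and scaffold loci pass through", {
  fx <- pop_small()
  pop <- fx$pop
  masked <- mask_to_scaffold(pop$panel, 200, seed = 3)
  prog <- pop$pedigree[!is.na(pop$pedigree$mother), ]
  fam <- prog[prog$mother == prog$mother[1] & prog$father == prog$father[1], ]
  obs <- masked$scaffold$dosage[fam$id, , drop = FALSE]
  res <- impute_family(pop$haplotypes, fam$mother[1], fam$father[1], obs,
                       masked$index)
  truth <- pop$panel$dosage[fam$id, , drop = FALSE]
  acc <- imputation_accuracy(res$imputed, truth)
  expect_gt(acc$acc_individuals, 0.9)
  expect_equal(unname(res$imputed[, masked$index]), unname(obs),
               ignore_attr = TRUE)
})

test_that("accuracy does not increase with the recombination rate", {
  fx <- pop_small()
  haps <- fx$pop$haplotypes
  acc_at <- function(rate) {
    set.seed(31)
    off <- simulate_cross(haps, "acc_001", "acc_002", 8, recomb_rate = rate)
    truth <- off$H1 + off$H2
    idx <- mask_to_scaffold(fx$pop$panel, 100, seed = 4)$index
    res <- impute_family(haps, "acc_001", "acc_002",
                         truth[, idx, drop = FALSE], idx)
    imputation_accuracy(res$imputed, truth)$acc_individuals
  }
  a_low <- acc_at(0.2); a_high <- acc_at(5)
  expect_gte(a_low, a_high)
  expect_gt(a_low, 0.9)
})
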