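test_that("VanRaden kinship has its closed-form structure", {
  # duplicated individual: all entries equal the diagonal value
  set.seed(11)
  row <- rbinom(50, 2, 0.4)
  dup <- matrix(rep(row, 6), 6, 50, byrow = TRUE,
                dimnames = list(paste0("i", 1:6), NULL))
  # add one polymorphic individual so markers are not all monomorphic
  dup[6, ] <- rbinom(50, 2, 0.4)
  K <- kinship_vanraden(make_panel(dup))
  expect_lt(max(abs(K[1:5, 1:5] - K[1, 1])), 1e-12)
  # opposite homozygotes, p_hat = 0.5: centered dosages +-1, so
  # K12 = -m / (2 * m * 0.25) = -2 and the normalized entry is -1
  opp <- make_panel(rbind(a = rep(0, 10), b = rep(2, 10)))
  K2 <- kinship_vanraden(opp)
  expect_equal(K2["a", "b"], -2)
  expect_equal(K2["a", "b"] / sqrt(K2["a", "a"] * K2["b", "b"]), -1)
  # monomorphic markers are excluded with a count
  mono <- make_panel(cbind(rbind(a = 0, b = 2, c = 1), m2 = c(2, 2, 2)))
  expect_message(kinship_vanraden(mono), "1 monomorphic")
  # full-sibs are more related than average unrelated accessions
  fx <- pop_small()
  Kp <- kinship_vanraden(fx$pop$panel)
  ped <- fx$pop$pedigree
  fam1 <- ped$id[!is.na(ped$mother) & ped$mother == ped$mother[81] &
                   ped$father == ped$father[81]]
  sib_pairs <- utils::combn(fam1, 2)
  sib_k <- mean(Kp[cbind(sib_pairs[1, ], sib_pairs[2, ])])
  acc <- ped$id[is.na(ped$mother)][1:40]
  acc_pairs <- utils::combn(acc, 2)
  acc_k <- mean(Kp[cbind(acc_pairs[1, ], acc_pairs[2, ])])
  expect_gt(sib_k, acc_k)
})

test_that("with identity kinship the first scan step is ordinary regression", {
  set.seed(6)
  dos <- matrix(rbinom(40 * 60, 2, 0.5), 40, 60,
                dimnames = list(paste0("i", 1:40), NULL))
  pan <- make_panel(dos)
  y <- stats::setNames(rnorm(40), rownames(dos))
  sc <- mlmm_scan(pan, y, K = diag(40), max_steps = 1)
  keep <- panel_maf(pan) >= 0.05
  p_ols <- apply(pan$dosage[, keep, drop = FALSE], 2, function(g) {
    stats::summary.lm(stats::lm(y ~ g))$coefficients[2, 4]
  })
  expect_lt(max(abs(sc$scan$p - p_ols)), 1e-8)
})

test_that("a strong planted QTL is picked as the first cofactor", {
  fx <- pop_small()
  pan <- fx$pop$panel
  set.seed(13)
  maf <- panel_maf(pan)
  j <- which(maf > 0.3)[25]
  g <- pan$dosage[, j]
  signal <- scale(g)[, 1]
  y <- stats::setNames(sqrt(0.4) * signal +
                         sqrt(0.6) * rnorm(nrow(pan$dosage)),
                       rownames(pan$dosage))
  sc <- mlmm_scan(pan, y)
  expect_gte(length(sc$cofactors), 1)
  hit <- sc$scan[sc$scan$marker == sc$cofactors[1], ]
  planted <- pan$map[j, ]
  same_chrom <- hit$chrom == planted$chrom
  expect_true(same_chrom && abs(hit$pos - planted$pos) <= 1e5)
  # explained variance of the planted SNP is reported and plausible
  expect_gt(sc$scan$r2[sc$scan$marker == sc$cofactors[1]], 0.2)
  # adding the cofactor never resurrects it as a weaker hit
  expect_true(all(sc$scan$p[sc$scan$is_cofactor] < sc$alpha_star))
})

test_that("region merging follows the windowed rule", {
  empty <- tibble::tibble(marker = character(0), chrom = character(0),
                          pos = numeric(0))
  expect_equal(nrow(merge_regions(empty)), 0)
  # two hits 5.3 Mb apart stay separate associations
  two <- tibble::tibble(marker = c("s1", "s2"), chrom = "3",
                        pos = c(1e6, 6.3e6))
  expect_equal(nrow(merge_regions(two, merge_window_bp = 1e6)), 2)
  # chain merging: 1.0 and 1.4 merge, 3.0 is separate
  three <- tibble::tibble(marker = c("s1", "s2", "s3"), chrom = "1",
                          pos = c(1.0e6, 1.4e6, 3.0e6))
  reg <- merge_regions(three, merge_window_bp = 1e6)
  expect_equal(nrow(reg), 2)
  expect_equal(reg$n_snps, c(2L, 1L))
  # different chromosomes never merge
  cross <- tibble::tibble(marker = c("s1", "s2"), chrom = c("1", "2"),
                          pos = c(1e6, 1.2e6))
  expect_equal(nrow(merge_regions(cross)), 2)
})

test_that("single-SNP explained variance matches simple regression", {
  x <- c(0, 1, 2, 0, 1, 2)
  expect_equal(snp_r2(x, 2 + 3 * x), 1)
  expect_equal(snp_r2(c(0, 0, 2, 2), c(1, 3, 1, 3)), 0)
  y <- c(1, 2, 3, 1, 2, 4)
  expect_equal(snp_r2(x, y), summary(stats::lm(y ~ x))$r.squared,
               tolerance = 1e-12)
  expect_equal(round(snp_r2(x, y), 3), 0.915)
  expect_true(is.na(snp_r2(rep(1, 4), 1:4)))
})

test_that("the Bonferroni threshold scales inversely with marker count", {
  ms <- c(100, 1000, 303239)
  stars <- 0.05 / ms
  expect_true(all(diff(stars) < 0))
  expect_equal(stars[3], 1.65e-7, tolerance = 1e-2)
})
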