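# Shared fixtures, built once per test run.

make_map <- function(m, chrom = "1", pos = NULL) {
  tibble::tibble(marker = paste0(chrom, "_m", seq_len(m)),
                 chrom = chrom,
                 pos = if (is.null(pos)) seq_len(m) * 100L else pos)
}

make_panel <- function(dosage, chrom = "1", pos = NULL, tier = "full") {
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- paste0("i", seq_len(nrow(dosage)))
  }
  genotype_panel(dosage, make_map(ncol(dosage), chrom, pos), tier = tier)
}

# small multi-family population reused across tests
.fix <- new.env()
pop_small <- function() {
  if (is.null(.fix$pop)) {
    cfg <- sim_config(n_accessions = 80, origin_counts = c(A = 40, B = 40),
                      n_families = 6, n_progeny = 40, n_chromosomes = 5,
                      n_snps_full = 2000, n_snps_scaffold = 200,
                      n_environments = 3, field_rows = 10, seed = 42)
    .fix$cfg <- cfg
    .fix$pop <- simulate_population(cfg)
  }
  list(cfg = .fix$cfg, pop = .fix$pop)
}

# balanced one-environment phenotype table
balanced_trees <- function(ng = 50, reps = 4, s2g = 2, s2e = 2, seed = 5,
                           env = "e1") {
  set.seed(seed)
  g <- stats::rnorm(ng, 0, sqrt(s2g))
  tibble::tibble(
    genotype = rep(paste0("g", seq_len(ng)), each = reps),
    environment = env, block = rep(seq_len(reps), ng),
    row = rep(seq_len(ng), each = reps), col = rep(seq_len(reps), ng),
    trait = "t",
    value = rep(g, each = reps) + stats::rnorm(ng * reps, 0, sqrt(s2e)))
}
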