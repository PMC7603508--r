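#' Simulation configuration
#'
#' Defaults reproduce the design of a large apple reference population:
#' 269 founder accessions in ten origin groups, 265 progeny from 27
#' full-sib parental combinations (as even as possible, 10 or 9 each),
#' 17 chromosomes, dual-density SNP panels, and day-of-year phenotypes
#' scored at up to 6 environments with 2 complete blocks each.
#'
#' @param n_accessions number of founder accessions.
#' @param origin_counts named integer vector of accessions per origin
#'   group; must sum to `n_accessions`.
#' @param n_families number of full-sib parental combinations.
#' @param n_progeny total progeny, distributed over families as evenly as
#'   possible.
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length_bp chromosome length in bp (all chromosomes equal).
#' @param n_snps_full total full-density SNP count across the genome.
#' @param n_snps_scaffold size of the nested low-density scaffold panel.
#' @param ld_decay_bp characteristic length (bp) of the founder haplotype
#'   copy process; larger values give slower LD decay.
#' @param maf_min minimum per-marker minor allele frequency enforced on
#'   founders, in (0, 0.5).
#' @param origin_shift_sd SD of the per-origin allele-frequency
#'   perturbation creating weak population structure.
#' @param recomb_rate expected crossovers per chromosome per meiosis
#'   (Haldane model, no interference).
#' @param trait_specs list of [trait_spec()] objects.
#' @param n_environments,blocks_per_environment,field_rows field-trial
#'   layout; each block holds one replicate of every genotype.
#' @param seed integer RNG seed.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_accessions = 269,
                       origin_counts = c(NEE = 28, WCE = 134, SE = 22, SEE = 10,
                                         ANZ = 8, CAN = 16, JPN = 9, USA = 34,
                                         ZAF = 2, U = 6),
                       n_families = 27,
                       n_progeny = 265,
                       n_chromosomes = 17,
                       chrom_length_bp = 2e6,
                       n_snps_full = 20000,
                       n_snps_scaffold = 1000,
                       ld_decay_bp = 2000,
                       maf_min = 0.05,
                       origin_shift_sd = 0.03,
                       recomb_rate = 1.5,
                       trait_specs = list(trait_spec()),
                       n_environments = 6,
                       blocks_per_environment = 2,
                       field_rows = 20,
                       seed = 1) {
  if (sum(origin_counts) != n_accessions) {
    stop("origin_counts must sum to n_accessions", call. = FALSE)
  }
  if (n_snps_scaffold > n_snps_full) {
    stop("n_snps_scaffold must not exceed n_snps_full", call. = FALSE)
  }
  if (maf_min <= 0 || maf_min >= 0.5) stop("maf_min must be in (0, 0.5)", call. = FALSE)
  counts <- c(n_accessions, n_families, n_progeny, n_chromosomes,
              n_snps_full, n_snps_scaffold, n_environments,
              blocks_per_environment, field_rows)
  if (any(counts <= 0)) stop("all counts must be positive", call. = FALSE)
  structure(as.list(environment()), class = "sim_config")
}

#' Trait architecture and variance decomposition for simulation
#'
#' Variance fractions are the target shares of the total phenotypic
#' variance at the tree level; they must be nonnegative and sum to 1.
#' Components are rescaled to match the fractions exactly in the realized
#' sample, so parameter-recovery tests see sampling noise only through
#' the estimator, not the generator.
#'
#' @param name trait label.
#' @param n_causal number of causal loci (trait architecture M).
#' @param var_genotype,var_environment,var_gxe,var_spatial,var_residual
#'   variance fractions of the genotype, environment, genotype-by-
#'   environment, planted spatial surface and residual components.
#' @param offset_days day-of-year baseline added to every value.
#' @param sd_total total phenotypic SD in days.
#' @return A list of class `trait_spec`.
#' @export
trait_spec <- function(name = "harvest_date", n_causal = 100,
                       var_genotype = 0.74, var_environment = 0.05,
                       var_gxe = 0.12, var_spatial = 0.04,
                       var_residual = 0.05,
                       offset_days = 250, sd_total = 10) {
  fr <- c(var_genotype, var_environment, var_gxe, var_spatial, var_residual)
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-8) {
    stop("variance fractions must be nonnegative and sum to 1", call. = FALSE)
  }
  structure(list(name = name, n_causal = n_causal,
                 fractions = c(genotype = var_genotype, environment = var_environment,
                               gxe = var_gxe, spatial = var_spatial,
                               residual = var_residual),
                 offset_days = offset_days, sd_total = sd_total),
            class = "trait_spec")
}

build_map <- function(config) {
  per_chrom <- rep(config$n_snps_full %/% config$n_chromosomes, config$n_chromosomes)
  extra <- config$n_snps_full %% config$n_chromosomes
  if (extra > 0) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1L
  purrr::map_dfr(seq_len(config$n_chromosomes), function(ch) {
    pos <- sort(sample.int(config$chrom_length_bp, per_chrom[ch]))
    tibble::tibble(
      marker = sprintf("snp_%d_%d", ch, seq_along(pos)),
      chrom = as.character(ch), pos = pos
    )
  })
}

markov_column <- function(prev, copy_prob, p_hap) {
  copy <- stats::runif(length(prev)) < copy_prob
  out <- stats::rbinom(length(prev), 1L, p_hap)
  out[copy] <- prev[copy]
  out
}

#' Simulate founder haplotypes with controllable LD decay
#'
#' Founder haplotypes follow a first-order copy process along each
#' chromosome: the allele at a marker copies the previous marker's allele
#' with probability `exp(-d / ld_decay_bp)` (d the bp gap), otherwise it
#' is drawn fresh from the marker's origin-specific allele frequency.
#' LD between adjacent markers therefore decays approximately
#' exponentially with distance. Each origin group receives a small
#' one-off allele-frequency shift so ordination shows weak clines.
#' Markers whose realized MAF falls below `maf_min` are redrawn
#' (conditional on the preceding marker) until the constraint holds.
#'
#' @param config a [sim_config()].
#' @return list with `haplotypes` (a `haplotype_set`: binary matrices
#'   `H1`, `H2`, the map, and a founder flag) and `panel`
#'   (a [genotype_panel()]).
#' @export
simulate_founders <- function(config) {
  set.seed(config$seed)
  map <- build_map(config)
  m <- nrow(map)
  n <- config$n_accessions
  origins <- rep(names(config$origin_counts), config$origin_counts)
  # keep frequencies away from the MAF floor so the rejection step can
  # succeed even after the origin-specific shift
  lo <- min(0.45, 1.5 * config$maf_min)
  base_p <- stats::runif(m, lo, 1 - lo)
  shift <- vapply(names(config$origin_counts), function(o) {
    stats::rnorm(m, 0, config$origin_shift_sd)
  }, numeric(m))
  p_orig <- pmin(pmax(base_p + shift, lo), 1 - lo)  # m x n_origins

  hap_origin <- rep(origins, each = 2L)          # 2n haplotypes
  oi <- match(hap_origin, names(config$origin_counts))
  H <- matrix(0L, nrow = 2L * n, ncol = m)
  gap <- c(Inf, diff(map$pos))
  gap[c(TRUE, map$chrom[-1] != map$chrom[-m])] <- Inf
  copy_prob <- exp(-gap / config$ld_decay_bp)
  copy_prob[!is.finite(gap)] <- 0

  H[, 1] <- stats::rbinom(2L * n, 1L, p_orig[1, oi])
  for (l in 2:m) {
    H[, l] <- markov_column(H[, l - 1L], copy_prob[l], p_orig[l, oi])
  }

  # enforce the MAF floor by redrawing offending columns given their
  # left neighbour (rare; weakens the link to the right neighbour only
  # at redrawn columns)
  maf <- function(col) { p <- mean(col) / 2; min(p, 1 - p) }
  dos <- H[seq(1, 2 * n, 2), ] + H[seq(2, 2 * n, 2), ]
  low <- which(apply(dos, 2, maf) < config$maf_min)
  for (l in low) {
    ok <- FALSE
    for (att in seq_len(100)) {
      prev <- if (l > 1 && is.finite(gap[l])) H[, l - 1L] else H[, l]
      cp <- if (l > 1) copy_prob[l] else 0
      cand <- markov_column(prev, cp, p_orig[l, oi])
      d <- cand[seq(1, 2 * n, 2)] + cand[seq(2, 2 * n, 2)]
      if (maf(d) >= config$maf_min) { H[, l] <- cand; ok <- TRUE; break }
    }
    if (!ok) stop("could not satisfy maf_min at marker ", map$marker[l],
                  " after 100 resampling attempts", call. = FALSE)
  }

  ids <- sprintf("acc_%03d", seq_len(n))
  H1 <- H[seq(1, 2 * n, 2), , drop = FALSE]
  H2 <- H[seq(2, 2 * n, 2), , drop = FALSE]
  rownames(H1) <- rownames(H2) <- ids
  haps <- structure(list(H1 = H1, H2 = H2, map = map,
                         founder = stats::setNames(rep(TRUE, n), ids)),
                    class = "haplotype_set")
  info <- tibble::tibble(id = ids, group = "accession", origin = origins)
  panel <- genotype_panel(H1 + H2, map, info, tier = "full")
  list(haplotypes = haps, panel = panel)
}

gamete_from <- function(h1, h2, map, recomb_rate) {
  out <- integer(length(h1))
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    ncx <- stats::rpois(1, recomb_rate)
    start <- sample(1:2, 1)
    if (ncx == 0) {
      out[idx] <- if (start == 1) h1[idx] else h2[idx]
    } else {
      cuts <- sort(stats::runif(ncx, min(map$pos[idx]), max(map$pos[idx])))
      seg <- findInterval(map$pos[idx], cuts)          # 0..ncx
      use1 <- (seg + start) %% 2 == 1                  # alternate haplotypes
      out[idx] <- ifelse(use1, h1[idx], h2[idx])
    }
  }
  out
}

#' Simulate a full-sib family by meiosis with Haldane crossovers
#'
#' Each gamete is a mosaic of the parent's two haplotypes with a
#' Poisson(`recomb_rate`) number of crossovers placed uniformly per
#' chromosome (no interference). Offspring are phased: `H1` carries the
#' maternal gamete, `H2` the paternal one, so trios are Mendelian-
#' consistent by construction.
#'
#' @param haps a `haplotype_set` containing both parents.
#' @param mother,father parent ids in `haps`.
#' @param n_offspring family size.
#' @param recomb_rate expected crossovers per chromosome.
#' @param ids offspring ids (default generated).
#' @return a `haplotype_set` for the offspring.
#' @export
simulate_cross <- function(haps, mother, father, n_offspring,
                           recomb_rate = 1.5, ids = NULL) {
  stopifnot(inherits(haps, "haplotype_set"))
  for (p in c(mother, father)) {
    if (!p %in% rownames(haps$H1)) stop("unknown parent id: ", p, call. = FALSE)
  }
  if (is.null(ids)) ids <- sprintf("%s_x_%s_%02d", mother, father, seq_len(n_offspring))
  m <- ncol(haps$H1)
  H1 <- matrix(0L, n_offspring, m, dimnames = list(ids, colnames(haps$H1)))
  H2 <- H1
  for (k in seq_len(n_offspring)) {
    H1[k, ] <- gamete_from(haps$H1[mother, ], haps$H2[mother, ], haps$map, recomb_rate)
    H2[k, ] <- gamete_from(haps$H1[father, ], haps$H2[father, ], haps$map, recomb_rate)
  }
  structure(list(H1 = H1, H2 = H2, map = haps$map,
                 founder = stats::setNames(rep(FALSE, n_offspring), ids)),
            class = "haplotype_set")
}

#' Simulate the whole reference population
#'
#' Founder accessions plus `n_families` full-sib families whose parents
#' are drawn (seeded) from the accessions, with `n_progeny` offspring
#' spread over families as evenly as possible.
#'
#' @param config a [sim_config()].
#' @return list with `panel` (all individuals, full density),
#'   `haplotypes` (phased, all individuals), `pedigree` (tibble
#'   `id`, `mother`, `father`; founders have `NA` parents) and
#'   `families` (tibble of parental combinations and sizes).
#' @export
simulate_population <- function(config) {
  fo <- simulate_founders(config)
  haps <- fo$haplotypes
  acc_ids <- rownames(haps$H1)
  pairs <- matrix(sample(acc_ids, 2L * config$n_families, replace = FALSE),
                  ncol = 2)
  sizes <- rep(config$n_progeny %/% config$n_families, config$n_families)
  extra <- config$n_progeny %% config$n_families
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  fam <- tibble::tibble(family = seq_len(config$n_families),
                        mother = pairs[, 1], father = pairs[, 2],
                        n_offspring = sizes)
  kids <- purrr::pmap(fam, function(family, mother, father, n_offspring) {
    simulate_cross(haps, mother, father, n_offspring, config$recomb_rate,
                   ids = sprintf("prog_%02d_%02d", family, seq_len(n_offspring)))
  })
  H1 <- do.call(rbind, c(list(haps$H1), purrr::map(kids, "H1")))
  H2 <- do.call(rbind, c(list(haps$H2), purrr::map(kids, "H2")))
  all_haps <- structure(list(H1 = H1, H2 = H2, map = haps$map,
                             founder = stats::setNames(rownames(H1) %in% acc_ids,
                                                       rownames(H1))),
                        class = "haplotype_set")
  ped <- dplyr::bind_rows(
    tibble::tibble(id = acc_ids, mother = NA_character_, father = NA_character_),
    purrr::pmap_dfr(fam, function(family, mother, father, n_offspring) {
      tibble::tibble(id = sprintf("prog_%02d_%02d", family, seq_len(n_offspring)),
                     mother = mother, father = father)
    })
  )
  info <- dplyr::bind_rows(
    fo$panel$info,
    tibble::tibble(id = setdiff(rownames(H1), acc_ids), group = "progeny",
                   origin = "progeny")
  )
  panel <- genotype_panel(H1 + H2, haps$map, info, tier = "full")
  list(panel = panel, haplotypes = all_haps, pedigree = ped, families = fam)
}

#' Mask a full-density panel to a scaffold subset
#'
#' Picks a deterministic, evenly spread (by map order) subset of
#' `n_snps_scaffold` markers, allocating per-chromosome counts by the
#' largest-remainder rule so every chromosome keeps floor(share) or
#' floor(share)+1 markers, with a seeded within-chromosome phase.
#'
#' @param panel full-density [genotype_panel()].
#' @param n_snps_scaffold scaffold size.
#' @param seed integer seed for the within-chromosome phase.
#' @return list with `scaffold` (a scaffold-tier [genotype_panel()]) and
#'   `index` (integer positions of scaffold markers in the full map).
#' @export
mask_to_scaffold <- function(panel, n_snps_scaffold, seed = 1) {
  M <- ncol(panel$dosage)
  if (n_snps_scaffold > M) stop("scaffold larger than panel", call. = FALSE)
  if (n_snps_scaffold == M) {
    return(list(scaffold = subset_panel(panel, tier = "scaffold"),
                index = seq_len(M)))
  }
  set.seed(seed)
  counts <- table(factor(panel$map$chrom, levels = unique(panel$map$chrom)))
  share <- as.numeric(counts) / M * n_snps_scaffold
  base <- floor(share)
  rem <- n_snps_scaffold - sum(base)
  if (rem > 0) {
    base[order(share - base, decreasing = TRUE)[seq_len(rem)]] <-
      base[order(share - base, decreasing = TRUE)[seq_len(rem)]] + 1
  }
  idx <- unlist(purrr::map(seq_along(counts), function(i) {
    mc <- as.integer(counts[i]); k <- base[i]
    if (k == 0) return(integer(0))
    stride <- mc / k
    phase <- stats::runif(1, 0, stride)
    local <- unique(pmin(mc, ceiling(phase + stride * (seq_len(k) - 1) + 1e-9)))
    while (length(local) < k) {       # fill collisions deterministically
      local <- sort(union(local, setdiff(seq_len(mc), local)[1]))
    }
    which(panel$map$chrom == names(counts)[i])[sort(local)]
  }))
  idx <- sort(idx)
  list(scaffold = subset_panel(panel, markers = idx, tier = "scaffold"),
       index = idx)
}

scale_to_var <- function(x, target_var) {
  if (target_var == 0) return(rep(0, length(x)))
  v <- stats::var(x)
  if (v < 1e-12) stop("component has no variance; cannot realize requested fraction",
                      call. = FALSE)
  (x - mean(x)) * sqrt(target_var / v)
}

spatial_surface <- function(rows, cols) {
  # 3 seeded Gaussian bumps + a linear trend; smooth enough for a
  # tensor P-spline to recover
  cr <- stats::runif(3, 1, rows); cc <- stats::runif(3, 1, cols)
  amp <- stats::rnorm(3, 0, 1); wid <- stats::runif(3, 0.2, 0.5)
  slope <- stats::rnorm(2, 0, 0.5)
  f <- function(u, v) {
    s <- slope[1] * u / rows + slope[2] * v / cols
    for (b in 1:3) {
      s <- s + amp[b] * exp(-((u - cr[b])^2 / (wid[b] * rows)^2 +
                              (v - cc[b])^2 / (wid[b] * cols)^2))
    }
    s
  }
  f
}

#' Simulate tree-level phenotypes over a multi-environment trial
#'
#' Each tree value is `offset + genotype effect + environment effect +
#' GxE deviation + spatial surface value at (row, col) + residual`, in
#' day-of-year units. Every component is rescaled so its realized
#' variance share of `sd_total^2` matches the [trait_spec()] fractions
#' exactly in the generated sample. Every genotype is planted once per
#' complete block per environment.
#'
#' @param panel [genotype_panel()] providing the genotypes (causal loci
#'   are sampled from its markers).
#' @param spec a [trait_spec()].
#' @param n_environments,blocks,field_rows layout; columns are derived
#'   so each block holds one replicate of every genotype.
#' @param seed integer seed.
#' @param round_days round values to whole days (default off, keeping
#'   estimator tests exact).
#' @return list with `trees` (tibble: `genotype`, `environment`, `block`,
#'   `row`, `col`, `trait`, `value`) and `truth` (causal loci and
#'   effects, true breeding values, environment effects, GxE deviations,
#'   spatial surfaces, realized fractions).
#' @export
simulate_phenotypes <- function(panel, spec, n_environments = 6, blocks = 2,
                                field_rows = 20, seed = 1, round_days = FALSE) {
  stopifnot(inherits(spec, "trait_spec"))
  set.seed(seed)
  ids <- rownames(panel$dosage)
  n <- length(ids)
  fr <- spec$fractions
  V <- spec$sd_total^2

  causal <- sort(sample.int(ncol(panel$dosage), spec$n_causal))
  eff <- stats::rnorm(spec$n_causal)
  tbv_raw <- as.numeric(panel$dosage[, causal, drop = FALSE] %*% eff)

  cols_per_block <- ceiling(n / field_rows)
  n_cols <- cols_per_block * blocks
  envs <- sprintf("env_%d", seq_len(n_environments))

  layout <- purrr::map_dfr(seq_len(n_environments), function(e) {
    purrr::map_dfr(seq_len(blocks), function(b) {
      slots <- tibble::tibble(
        row = rep(seq_len(field_rows), times = cols_per_block),
        col = rep((b - 1) * cols_per_block + seq_len(cols_per_block),
                  each = field_rows)
      )[seq_len(n), ]
      dplyr::mutate(slots, genotype = sample(ids), environment = envs[e],
                    block = b)
    })
  })

  g <- scale_to_var(tbv_raw, fr["genotype"] * V)
  names(g) <- ids
  l_raw <- stats::rnorm(n_environments)
  gxe_raw <- matrix(stats::rnorm(n * n_environments), n, n_environments,
                    dimnames = list(ids, envs))

  gi <- g[layout$genotype]
  lj <- if (fr["environment"] > 0) {
    scale_to_var(l_raw[match(layout$environment, envs)], fr["environment"] * V)
  } else rep(0, nrow(layout))
  ge <- if (fr["gxe"] > 0) {
    scale_to_var(gxe_raw[cbind(match(layout$genotype, ids),
                               match(layout$environment, envs))], fr["gxe"] * V)
  } else rep(0, nrow(layout))
  surfaces <- purrr::map(envs, ~spatial_surface(field_rows, n_cols))
  names(surfaces) <- envs
  sp_raw <- purrr::map2_dbl(layout$environment, seq_len(nrow(layout)),
                            function(e, i) surfaces[[e]](layout$row[i], layout$col[i]))
  # centre the surface within each environment: a between-environment
  # mean shift is indistinguishable from an environment effect
  sp_raw <- sp_raw - stats::ave(sp_raw, layout$environment)
  sp <- if (fr["spatial"] > 0) scale_to_var(sp_raw, fr["spatial"] * V) else rep(0, nrow(layout))
  res <- if (fr["residual"] > 0) {
    scale_to_var(stats::rnorm(nrow(layout)), fr["residual"] * V)
  } else rep(0, nrow(layout))

  value <- spec$offset_days + gi + lj + ge + sp + res
  if (round_days) value <- round(value)
  trees <- dplyr::mutate(layout, trait = spec$name, value = value)
  trees <- dplyr::select(trees, genotype, environment, block, row, col, trait, value)

  realized <- c(genotype = stats::var(gi), environment = stats::var(lj),
                gxe = stats::var(ge), spatial = stats::var(sp),
                residual = stats::var(res))
  realized <- realized / sum(realized)
  truth <- list(
    causal = tibble::tibble(trait = spec$name,
                            marker = panel$map$marker[causal], index = causal,
                            effect = eff),
    tbv = tibble::tibble(genotype = ids, tbv = unname(g)),
    env_effects = tibble::tibble(environment = layout$environment, effect = lj) |>
      dplyr::distinct(environment, .keep_all = TRUE),
    spatial = dplyr::distinct(dplyr::mutate(layout, surface = sp),
                              environment, row, col, surface),
    realized_fractions = realized
  )
  list(trees = trees, truth = truth)
}
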