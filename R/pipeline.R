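#' Run the full analysis pipeline end to end
#'
#' Orchestrates simulate -> impute-eval -> LD -> structure -> spatial
#' adjustment -> heritability/variance decomposition -> LS-means ->
#' GWAS -> genomic prediction -> density grid -> precision, writing each
#' stage's artifacts under `out_dir` (VCF, TSV/CSV, newick, JSON) and
#' returning a consolidated report. Stages communicate only via on-disk
#' artifacts plus the returned objects; the report contains no
#' timestamps, so identical config + seed gives a byte-identical report
#' file.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @param cv_repetitions repetitions for the prediction stage.
#' @param grid_densities,grid_seeds,grid_cv_repetitions density-grid
#'   settings (`NULL` densities skips the grid stage).
#' @param ld_fraction marker fraction for LD pair sampling.
#' @param profile_ci compute profile-likelihood CIs in the
#'   multi-environment fit.
#' @return list of class `pipeline_report` (also written as
#'   `report.json`): per-stage metrics, plus a `manifest` of artifact
#'   paths and wall times (the manifest is not part of the report file).
#' @export
run_pipeline <- function(config, out_dir,
                         cv_repetitions = 10,
                         grid_densities = NULL, grid_seeds = 3,
                         grid_cv_repetitions = 5,
                         ld_fraction = 0.1, profile_ci = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  tic <- function() proc.time()[["elapsed"]]
  stage_files <- function(stage, files, t0) {
    manifest[[stage]] <<- list(files = files, wall_s = tic() - t0)
  }

  ## 1. simulate ------------------------------------------------------
  t0 <- tic()
  pop <- simulate_population(config)
  masked <- mask_to_scaffold(pop$panel, config$n_snps_scaffold, seed = config$seed)
  phen <- purrr::map(config$trait_specs, function(sp) {
    simulate_phenotypes(pop$panel, sp, n_environments = config$n_environments,
                        blocks = config$blocks_per_environment,
                        field_rows = config$field_rows, seed = config$seed)
  })
  trees <- dplyr::bind_rows(purrr::map(phen, "trees"))
  f_vcf <- file.path(out_dir, "genotypes_full.vcf")
  f_svcf <- file.path(out_dir, "genotypes_scaffold.vcf")
  f_ped <- file.path(out_dir, "pedigree.tsv")
  f_map <- file.path(out_dir, "marker_map.tsv")
  f_phe <- file.path(out_dir, "phenotypes.csv")
  write_vcf(pop$panel, f_vcf, phased = TRUE)
  write_vcf(masked$scaffold, f_svcf)
  write_pedigree(pop$pedigree, f_ped)
  write_marker_map(pop$panel$map, f_map)
  write_phenotypes(trees, f_phe)
  jsonlite::write_json(
    purrr::map(phen, function(ph) list(
      causal = ph$truth$causal,
      realized_fractions = as.list(ph$truth$realized_fractions))),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  stage_files("simulate", c(f_vcf, f_svcf, f_ped, f_map, f_phe), t0)

  ## 2. imputation evaluation -----------------------------------------
  t0 <- tic()
  prog_ids <- pop$pedigree$id[!is.na(pop$pedigree$mother)]
  scaffold_prog <- subset_panel(masked$scaffold, individuals = prog_ids)
  imp <- impute_pedigree(pop$haplotypes, scaffold_prog, pop$pedigree,
                         masked$index)
  truth_dos <- pop$panel$dosage[rownames(imp$imputed), , drop = FALSE]
  acc <- imputation_accuracy(imp$imputed, truth_dos)
  imp_metrics <- list(
    acc_individuals = acc$acc_individuals, acc_markers = acc$acc_markers,
    fraction_imputed = fraction_imputed(ncol(scaffold_prog$dosage),
                                        ncol(pop$panel$dosage)))
  write_results_json("impute_eval", list(n_progeny = length(prog_ids)),
                     config$seed, imp_metrics,
                     file.path(out_dir, "impute_eval.json"))
  stage_files("impute_eval", file.path(out_dir, "impute_eval.json"), t0)

  ## 3. LD -------------------------------------------------------------
  t0 <- tic()
  pairs <- ld_sample_pairs(pop$panel, fraction = ld_fraction, seed = config$seed)
  dec <- ld_decay(pairs)
  pruned <- ld_prune(pop$panel)
  readr::write_tsv(tibble::tibble(marker = pop$panel$map$marker[pruned]),
                   file.path(out_dir, "ld_pruned_markers.tsv"))
  ld_metrics <- list(
    n_pairs = nrow(pairs),
    threshold_dist_bp = dec$threshold_dist_bp,
    window_means = stats::setNames(as.list(dec$window_means$mean_r2),
                                   paste0("bp_", dec$window_means$ref_bp)),
    n_pruned_retained = length(pruned))
  write_results_json("ld", list(fraction = ld_fraction), config$seed,
                     ld_metrics, file.path(out_dir, "ld.json"))
  stage_files("ld", file.path(out_dir, c("ld.json", "ld_pruned_markers.tsv")), t0)

  ## 4. structure -------------------------------------------------------
  t0 <- tic()
  acc_panel <- subset_panel(pop$panel,
                            individuals = which(pop$panel$info$group == "accession"))
  prog_panel <- subset_panel(pop$panel,
                             individuals = which(pop$panel$info$group == "progeny"))
  tr <- nj_tree(gt_distance(acc_panel))
  ape::write.tree(tr, file.path(out_dir, "nj_accessions.nwk"))
  pca <- pca_supplementary(acc_panel, prog_panel, n_components = 5)
  readr::write_tsv(pca$scores, file.path(out_dir, "pca_scores.tsv"))
  structure_metrics <- list(pc1_pc2_explained = sum(pca$explained[1:2]))
  stage_files("structure",
              file.path(out_dir, c("nj_accessions.nwk", "pca_scores.tsv")), t0)

  ## 5. phenotype models ------------------------------------------------
  t0 <- tic()
  pheno_metrics <- list()
  lsm_all <- list()
  for (sp in config$trait_specs) {
    tr_t <- trees[trees$trait == sp$name, ]
    adj <- spatial_adjust_all(tr_t)
    h2_raw <- h2_individual(tr_t)
    h2_adj <- h2_individual(adj$adjusted)
    retained <- exclude_low_h2(h2_adj)
    adj_ret <- adj$adjusted[adj$adjusted$environment %in% retained$environment, ]
    me <- fit_multienv(adj_ret, ci = profile_ci)
    lsm <- ls_means(adj_ret)
    lsm_all[[sp$name]] <- lsm
    pheno_metrics[[sp$name]] <- list(
      h2_individual_raw = mean(h2_raw$H2),
      h2_individual_adjusted = mean(h2_adj$H2),
      n_retained_environments = nrow(retained),
      h2_multi = me$heritability$H2,
      fractions = stats::setNames(as.list(me$varcomp$fraction),
                                  me$varcomp$component))
  }
  readr::write_csv(dplyr::bind_rows(lsm_all), file.path(out_dir, "ls_means.csv"))
  write_results_json("pheno", list(), config$seed, pheno_metrics,
                     file.path(out_dir, "pheno.json"))
  stage_files("pheno", file.path(out_dir, c("ls_means.csv", "pheno.json")), t0)

  ## 6-7. GWAS + prediction ---------------------------------------------
  t0 <- tic()
  K <- kinship_vanraden(pop$panel)
  eig <- eigen(K, symmetric = TRUE)
  gwas_metrics <- list(); pred_metrics <- list()
  for (nm in names(lsm_all)) {
    yv <- stats::setNames(lsm_all[[nm]]$lsmean, lsm_all[[nm]]$genotype)
    scan <- mlmm_scan(pop$panel, yv, eig = eig)
    readr::write_tsv(scan$scan, file.path(out_dir, paste0("gwas_", nm, ".tsv")))
    gwas_metrics[[nm]] <- list(n_regions = scan$n_regions,
                               n_cofactors = length(scan$cofactors))
    cv <- cross_validate(pop$panel, yv, repetitions = cv_repetitions,
                         seed = config$seed)
    pred_metrics[[nm]] <- list(ability = cv$ability,
                               ability_pooled = cv$ability_pooled)
  }
  write_results_json("gwas_predict", list(cv_repetitions = cv_repetitions),
                     config$seed, c(gwas_metrics, predict = list(pred_metrics)),
                     file.path(out_dir, "gwas_predict.json"))
  stage_files("gwas_predict", file.path(out_dir, "gwas_predict.json"), t0)

  ## 8. density grid ----------------------------------------------------
  grid_metrics <- NULL
  if (!is.null(grid_densities)) {
    t0 <- tic()
    nm <- names(lsm_all)[1]
    yv <- stats::setNames(lsm_all[[nm]]$lsmean, lsm_all[[nm]]$genotype)
    dg <- density_grid(pop$panel, yv, densities = grid_densities,
                       seeds_per_density = grid_seeds,
                       cv_repetitions = grid_cv_repetitions,
                       scaffold_index = masked$index,
                       seed = config$seed)
    readr::write_tsv(dg$results, file.path(out_dir, "density_grid.tsv"))
    grid_metrics <- list(trait = nm,
                         max_mean_ability = max(dg$summary$mean_ability))
    stage_files("density_grid", file.path(out_dir, "density_grid.tsv"), t0)
  }

  ## 9. precision -------------------------------------------------------
  t0 <- tic()
  pg <- precision_grid()
  readr::write_tsv(pg, file.path(out_dir, "precision_grid.tsv"))
  stage_files("precision", file.path(out_dir, "precision_grid.tsv"), t0)

  report <- list(
    seed = config$seed,
    n_individuals = nrow(pop$panel$dosage),
    n_markers = ncol(pop$panel$dosage),
    impute_eval = imp_metrics, ld = ld_metrics,
    structure = structure_metrics, pheno = pheno_metrics,
    gwas = gwas_metrics, predict = pred_metrics,
    density_grid = grid_metrics,
    precision_very_high_share = mean(pg$very_high))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(c(report, list(manifest = manifest)), class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> seed", x$seed, "-", x$n_individuals, "individuals x",
      x$n_markers, "markers\n")
  cat("  stages:", paste(names(x$manifest), collapse = ", "), "\n")
  invisible(x)
}
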