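# orchardgp

Quantitative-genetics tooling for *reference populations* of clonally
propagated crops: collections of named accessions plus full-sib progeny,
grafted as replicated trees across multi-environment field trials and
genotyped at two SNP-array densities. The package was built around the
design of a 534-genotype apple reference population (269 accessions in
ten origin groups plus 265 progeny from 27 parental combinations,
planted in six European countries in two complete blocks each), but
every design count is a parameter.

It covers the full analysis chain for such a population, with a seeded
simulator providing ground truth for every stage:

* **Simulation** — founder haplotypes with tunable LD decay (first-order
  copy process), full-sib meiosis (Haldane crossovers), nested
  dual-density SNP panels, and tree-level day-of-year phenotypes with
  planted spatial surfaces, environment effects, G×E and residual noise
  at exact variance fractions.
* **Imputation** — family-based transmission tracing from a low-density
  scaffold panel to full density, scored by the Pearson accuracy metrics
  used for array imputation (mean correlation across individuals and
  across markers).
* **LD** — pairwise genotype r², loess decay curves with the
  0.2-threshold distance, windowed means, and sliding-window pruning
  (50-SNP windows, step 10, r² > 0.1).
* **Structure** — allele-sharing distances, neighbor-joining trees
  (via ape), and PCA with supplementary individuals (progeny projected
  onto accession-trained axes).
* **Phenotypes** — per-environment spatial adjustment with a
  tensor-product P-spline plus random genotype/row/column effects
  (via mgcv), clonal-mean heritability

  `H² = σ²_g / σ²_p`, with `σ²_p = σ²_g + σ²_ε/n̄_r` (one location) or
  `σ²_p = σ²_g + σ²_gl/n_l + σ²_ε/(n_l n̄_r)` (multi-location),

  REML variance decomposition with profile-likelihood CIs (via lme4),
  the < 0.1-heritability trial-exclusion rule, and LS-means of genotypes
  across environments.
* **GWAS** — multi-locus mixed model (MLMM): stepwise cofactor selection
  under a VanRaden-kinship polygenic background, spectral REML for the
  variance ratio, Bonferroni threshold α* = α/m, region merging and
  per-SNP explained variance r².
* **Genomic prediction** — RR-BLUP `y = 1µ + G u + ε`,
  `u ~ N(0, I σ²_u)`, solved in primal or dual (GBLUP-kernel) form, with
  repeated 5-fold cross-validation reporting predictive ability
  (Pearson r in held-out folds).
* **Density experiments** — GWAS hit counts and predictive ability over
  evenly spaced, scaffold-array, and LD-thinned marker subsets with 95%
  CIs across seeds.
* **Precision** — the closed-form expected precision of GEBVs,
  `r̂² ≅ N h² / (N h² + M (1 − h²))`, over design grids with
  oligogenic/complex/very-complex architecture classes.

Everything is tidyverse-shaped: functions take and return tibbles,
fitted objects have `tidy()`/`glance()` methods, and each result type
has an `autoplot()`.

## Worked example

```r
library(orchardgp)

cfg <- sim_config(n_accessions = 120, origin_counts = c(A = 60, B = 60),
                  n_families = 8, n_progeny = 60, n_snps_full = 2000,
                  n_snps_scaffold = 200, n_environments = 3,
                  field_rows = 12, seed = 3)
pop <- simulate_population(cfg)
ph  <- simulate_phenotypes(pop$panel, trait_spec(), n_environments = 3,
                           blocks = 2, field_rows = 12, seed = 11)

adj <- spatial_adjust_all(ph$trees)
me  <- fit_multienv(adj$adjusted, ci = FALSE)
me$varcomp
#> # A tibble: 4 × 5
#>   component           variance fraction ci_lower ci_upper
#>   <chr>                  <dbl>    <dbl>    <dbl>    <dbl>
#> 1 environment (fixed)     5.25   0.0741       NA       NA
#> 2 genotype               51.1    0.722        NA       NA
#> 3 gxe                     5.32   0.0751       NA       NA
#> 4 residual                9.14   0.129        NA       NA

lsm  <- ls_means(adj$adjusted)
scan <- mlmm_scan(pop$panel, lsm)
scan
#> <gwas_scan> 2000 SNPs tested, Bonferroni alpha* = 2.5e-05
#> ...

cv <- cross_validate(pop$panel, lsm, repetitions = 5, seed = 2)
cv
#> <cv_result> 5 x 5-fold CV
#>   mean predictive ability (per-fold) = 0.472, pooled = 0.459
```

The simulated trait uses the harvest-date-like decomposition (genotype
0.74, environment 0.05, G×E 0.12, spatial 0.04, residual 0.05 of total
variance); the REML fit recovers those shares (after the spatial part is
adjusted away) and the genotype LS-means drive the downstream scan and
prediction. `run_pipeline(cfg, out_dir)` chains all stages and writes
VCF/TSV/CSV/JSON artifacts plus a consolidated `report.json`.

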