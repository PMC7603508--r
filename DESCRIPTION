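Package: orchardgp
Title: Simulation and Quantitative Genetics of Clonally Replicated
    Multi-Environment Breeding Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and analysing reference populations of
    clonally propagated crops genotyped at two SNP-array densities and
    phenotyped across multi-environment field trials. Provides a seeded
    population simulator (founder haplotypes with tunable linkage
    disequilibrium decay, full-sib families, dual-density panels,
    tree-level day-of-year phenotypes with planted spatial surfaces),
    family-based marker imputation with accuracy metrics, linkage
    disequilibrium decay summaries and sliding-window pruning,
    neighbor-joining trees and principal component analysis with
    supplementary individuals, spatial adjustment of field trials with
    tensor-product P-splines, clonal-mean heritability and variance
    decomposition by REML, multi-locus mixed-model association scans with
    genomic kinship, ridge-regression BLUP genomic prediction with
    repeated cross-validation, SNP-density experiments, and closed-form
    precision of genomic estimated breeding values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    mgcv,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
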