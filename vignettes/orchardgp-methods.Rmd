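---
title: "Models and methods in orchardgp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in orchardgp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

orchardgp analyses reference populations of clonally propagated crops:
named accessions and full-sib progeny, replicated as grafted trees over
multi-environment trials, genotyped at two SNP-array densities. This
vignette explains the models behind each stage, the parameters that
matter, the numerical choices, and what the synthetic data generator
does and does not emulate.

## The synthetic population

The generator's defaults encode the design the package was built
around: 269 accessions split over ten origin groups (NEE 28, WCE 134,
SE 22, SEE 10, ANZ 8, CAN 16, JPN 9, USA 34, ZAF 2, plus 6 of unknown
origin) and 265 progeny from 27 parental combinations, spread 10/10/…/9
per family; 17 chromosomes; 6 environments with 2 complete blocks each.
All of these are `sim_config()` parameters.

**Founder haplotypes.** Each haplotype follows a first-order
copy/mutate process along the chromosome: the allele at marker *l*
copies marker *l − 1*'s allele with probability `exp(-d / ld_decay_bp)`
(*d* the bp gap), otherwise it is drawn fresh from the marker's allele
frequency. Adjacent-marker correlation therefore decays approximately
exponentially with distance, which is the only LD feature downstream
stages depend on; a coalescent simulator would add realism (allele
frequency spectra, variable recombination) that none of the estimators
here exploit. `ld_decay_bp` (default 2 kb) sets the decay scale — with
the default marker spacing this puts the r² = 0.2 crossing in the
low-kb range, the regime of a diverse outcrossing tree crop. Base
frequencies are uniform on an interval bounded away from the MAF floor
(1.5 × `maf_min`) so the floor can be enforced by resampling; markers
whose realized MAF still falls below `maf_min` are redrawn conditional
on their left neighbour (the link to the right neighbour is refreshed
for those rare columns). Each origin group receives a one-off
N(0, `origin_shift_sd` = 0.03) frequency perturbation per marker,
producing the weak clinal structure visible on the first principal
components — deliberately weak, as in diverse cultivated germplasm.

**Meiosis.** Gametes are parental-haplotype mosaics with a
Poisson(`recomb_rate`) crossover count per chromosome and uniform
crossover positions (Haldane model, no interference; default 1.5
crossovers per chromosome). Offspring are stored phased (maternal and
paternal gametes separately), which makes trios Mendelian-consistent by
construction and gives the imputation stage its truth phases.

**Phenotypes.** Each tree's value is

```
offset + g(genotype) + l(environment) + gl(genotype, environment)
       + f(row, col) + ε
```

in day-of-year units (real-valued by default; integer rounding is a
flag so estimator tests remain exact). True breeding values are sums of
`n_causal` marker dosages times N(0, 1) effects; G×E deviations are
independent normal per genotype × environment cell; the planted surface
per environment is three seeded Gaussian bumps plus a linear trend —
smooth by construction, hence recoverable by a tensor-product spline;
residuals are iid normal. Every component is rescaled so its realized
variance share of `sd_total²` matches the `trait_spec()` fractions
exactly in the generated sample (the default is the harvest-date-like
decomposition: genotype 0.74, environment 0.05, G×E 0.12, spatial 0.04,
residual 0.05). Two subtleties: the surface is centred within each
environment, because a between-environment mean shift in the surface is
statistically indistinguishable from an environment effect; and the
genotype component is scaled at the genotype level, so tree-level
realized fractions differ from targets only by the balanced-expansion
factor (negligible at the default sizes). What the generator does *not*
emulate: demographic history, selection, triploids, missing-data
patterns of real arrays, genotype-specific spatial interactions, and
multi-year phenology.

The paper-style progeny choice (genetic-distance sampling within
families) is not emulated: all simulated progeny are kept. Nothing
downstream conditions on the within-family sampling scheme, and keeping
everything makes family sizes exact.

## Imputation and its metrics

Family imputation is a minimal-switch transmission tracer, not a
haplotype-cluster HMM. Per offspring chromosome, the hidden state is
which of the four (maternal, paternal) haplotype pairs is being
transmitted; scaffold markers are the observations. A haplotype switch
costs `switch_penalty` (2.0) and a genotype mismatch `mismatch_cost`
(1.5), so one crossover (cost 2) is cheaper than two genotyping errors
(cost 3). A forward/backward pass over the scaffold anchors yields, at
each anchor, the set of globally optimal states; between anchors the
expected transmitted allele averages the flanking anchors' optimal
states with equal weights, so fully uninformative stretches give
expected dosage 1 rather than an arbitrary hard call. Scaffold
genotypes impossible under every state (opposing homozygotes) are
flagged and excluded; scaffold loci otherwise pass through unchanged.
Accuracy is reported exactly as array-imputation studies report it:
the mean over individuals of the per-individual Pearson correlation
between imputed and true dosages, and the mean over markers of the
per-marker correlation. Zero-variance rows or columns make the
correlation undefined; they are excluded and counted, never imputed as
zero, which would bias the mean toward zero on uninformative panels.
Whether such published metrics average per-row/column correlations or
pool all entries is usually ambiguous; the per-row/column mean is used
here and stated in the output.

## LD, structure

LD is the squared Pearson correlation of dosages (composite LD): it
needs no phase and is what array studies compute. Decay summaries fit
`stats::loess` (local quadratic, tricube weights, span = 0.5) of r²
against distance, evaluate it on a 200-point log-spaced grid, and
report the first crossing below 0.2 with linear interpolation — if the
curve is already below the threshold at the first evaluable distance,
that distance is reported. Windowed means use a ±50 bp window around
each reference distance (0.1, 1, 5, 100 kb). Pruning follows the
PLINK-style sliding rule: windows of 50 SNPs advanced by 10; while any
retained pair in the window exceeds r² = 0.1 the later marker of the
offending pair is removed (earlier marker kept on ties, so the
procedure is deterministic). The pruned set is the documented input for
external model-based structure tools, which are out of scope here.

Distances between individuals default to allele-sharing dissimilarity
(mean |dosage difference| / 2 ∈ [0, 1]); Euclidean is a flag.
Neighbor joining is `ape::nj`; negative branch lengths are clamped to
zero with the length moved to the adjacent edge. PCA with supplementary
individuals centres markers on the *active* individuals only (the
accessions), takes loadings from the active covariance, and projects
the progeny afterwards, so related progeny cannot distort the axes.
Markers are not scaled to unit variance by default — dosage variance
carries frequency information — but a `scale.` flag exists since array
studies differ on this.

## Spatial adjustment, heritability, LS-means

Within each environment the tree-level model is

```
y = f(row, col) + Z_g c_g + Z_r c_r + Z_c c_c + ε
```

with a tensor-product cubic P-spline surface (second-order difference
penalty, knots every ~4 rows/columns, anisotropic smoothing) and
independent random genotype, row and column effects. The fit uses
`mgcv::bam(method = "fREML", discrete = TRUE)`, the standard fast-REML
penalized-spline engine; a single te() smooth replaces the five-part
PS-ANOVA decomposition some field-trial packages use — the adjusted
values, which are the contract of this stage, are unchanged by that
simplification, and effective dimensions (trace-based edf) are reported
per component. The adjusted value of a tree is intercept + genotype
effect + that tree's residual, i.e. the surface and row/column effects
are removed. Layouts with fewer than three distinct rows (or columns)
degrade to a 1D smooth with a warning. Coordinates are used as given
integers.

Clonal-mean heritability uses the one-way random-effects model per
environment, `H² = σ²_g / (σ²_g + σ²_ε/n̄_r)`, with `n̄_r` the
arithmetic mean of replicate counts (harmonic behind a flag). Trials
with H² < 0.1 are excluded before pooling — on such data the genotype
signal is too weak to justify the clonal-mean machinery. The pooled
model has fixed environment, random genotype and random G×E;
multi-location `H² = σ²_g / (σ²_g + σ²_gl/n_l + σ²_ε/(n_l n̄_r))`. Both
fits use lme4 REML; on balanced designs they agree with the closed-form
ANOVA estimators to numerical precision, which the tests assert as an
oracle. The fixed-environment variance fraction is the variance of the
fitted values with all random effects zeroed, over the total (fixed
variance + the three variance components). 95% profile-likelihood CIs
come from `confint(method = "profile")` on the SD scale and are
squared; when profiling fails at a boundary (a variance estimated at
zero) the lower bound is reported as 0. LS-means fit the additive
two-way OLS model and average `µ̂ + ĝ_i + l̂_j` over all retained
environments, which is exactly the normal-equations LS-mean; a
disconnected genotype × environment design is refused with its
components named.

## GWAS and genomic prediction

The scan is a multi-locus mixed model: `y = X b + u + ε` with
`u ~ N(0, K σ²_g)` and K the VanRaden genomic relationship matrix
(dosages centred by 2p̂, denominator `2 Σ p̂(1−p̂)`, monomorphic markers
dropped with a count; MAF < 0.05 markers excluded from testing). One
spectral decomposition of K is reused throughout; per step, the
variance ratio δ = σ²_ε/σ²_g is re-estimated by REML with Brent search
on log δ ∈ [−10, 10] (tolerance 1e−6), and every non-cofactor SNP gets
a GLS Wald t-test in the rotated, whitened space (per-SNP residual
variance, so with K = I the p-values equal ordinary regression exactly
— an oracle the tests assert). Forward selection adds the minimum-p SNP
while p < α* = α/m; a backward pass re-tests each cofactor in the final
model and drops any that rose above α*. This deterministic
Bonferroni-stop rule replaces software-specific model-selection
defaults, and m always counts the markers actually tested, so the
threshold adapts when the density experiment subsets markers.
Significant SNPs within 1 Mb on a chromosome merge into one region —
"region" has no standard width, and 1 Mb preserves reported
associations a few Mb apart as separate hits. Per-SNP explained
variance is the r² of the simple regression of the LS-means on that
SNP's dosage.

RR-BLUP solves `y = 1µ + G u + ε`, `u ~ N(0, I σ²_u)`, with markers
centred by 2p̂ and unscaled (the RR-BLUP convention; scaling is a
flag). The design matrix relating genotypes to observations is the
identity because y holds one LS-mean per genotype. Variance components
come from spectral REML on the equivalent GBLUP kernel GG′; the dual
(n × n) solve is the default since markers vastly outnumber
individuals, and the primal mixed-model equations are kept as an
equivalence oracle. Cross-validation partitions genotypes into 5 folds,
re-estimates the ridge parameter inside every training fold (no
leakage), and reports predictive ability as the per-fold Pearson
correlation averaged within and then across repetitions; the pooled
correlation per repetition is reported alongside since published
definitions vary. Folds with fewer than 3 genotypes cause the
repetition to be resampled. Note the small negative bias of null CV
correlations (order −1/fold size): it is why error-control checks are
run at the study-scale fold size.

The density experiment evaluates evenly spaced subsets (stride ⌊M/m⌋
from a seeded random start, marker order as the distance proxy) at each
density × seed, plus the scaffold-array subset and the LD-pruned subset
once each. Kinship always comes from the full panel, so density varies
only the tested markers — the point of the experiment is the marker
set, not the relationship estimates. Means get normal-approximation 95%
CIs over seeds (t-quantiles behind a flag; with 10 seeds the difference
is cosmetic).

Expected GEBV precision uses the closed form
`r̂² = N h² / (N h² + M (1 − h²))` with architecture classes oligogenic
(M ≤ 10), complex (10 < M ≤ 100), very complex (100 < M ≤ 1000) and a
very-high-precision flag at r̂² ≥ 0.8. M = 0 returns 1, the formula's
no-noise-loci limit; h² = 0 returns 0 with a warning.

## Problem sizes and numerical choices in the tests

The test suite exercises the full design at 534 genotypes (269 + 265 in
27 families) with 2,000–20,000 SNPs depending on the stage: variance
recovery and spatial checks on 534 × 5 environments × 2 blocks
(~5,300 trees), error control on 50 null traits over a 534 × 5,000
panel, and the density experiment on a 534 × 20,000 panel at densities
500–20,000 with 5 seeds × 10 CV repetitions. These sizes give each
estimator enough data that parameter-recovery tolerances (±0.05 on
variance fractions, ±0.1 on null ability, 0.9 on surface correlation)
reflect estimator behaviour rather than sampling luck, while a full
test run stays in the minutes range on one core. Unit fixtures are
smaller (dozens of genotypes, hundreds of markers) and are generated in
code at test time.

Determinism is a contract throughout: every stochastic operation takes
a seed, identical config + seed reproduce populations, fold
assignments, subsets and the pipeline report byte for byte, and the
report JSON deliberately contains no timestamps (wall times live in the
run manifest instead).

## Known limitations

The imputation baseline traces transmissions within genotyped-parent
families only; it neither phases unrelated founders nor imputes from
population haplotype frequencies, so its accuracies are not comparable
to population-based imputation software on unrelated panels. The LD
smoother is loess with span 0.5 — threshold distances inherit loess's
boundary behaviour and should be read on the evaluation grid. The
spatial model assumes an additive smooth surface shared by all
genotypes. The MLMM stops on a Bonferroni rule rather than an
information criterion, so on traits with many mid-sized QTL it is
conservative. Precision from the closed form assumes the M effective
loci act additively with a common information contribution; it is a
design heuristic, not an estimator.
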