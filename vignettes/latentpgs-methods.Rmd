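---
title: "Models and methods behind latentpgs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind latentpgs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(latentpgs)
```

latentpgs implements a complete inference chain for studying whether a set
of correlated behavioural phenotypes — and the polygenic risk behind them —
organizes into one general dimension or separate internalizing and
externalizing dimensions. The chain runs: genotype quality control and
two-stage ancestry PCA; polygenic score (PGS) construction; confirmatory
factor analysis (CFA) with a measurement-invariance ladder; LD-score
regression (LDSC) and a genetic-covariance factor model; per-SNP latent
factor weights and latent PGSs; and PGS–factor association models. A
synthetic-data module generates every input with known ground truth, which
is how the whole chain is tested.

This vignette explains the models, the defaults, and the design choices
made where the design was genuinely open. It states no empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## The phenotypic measurement model

`fit_cfa()` fits a confirmatory factor model by minimizing the maximum
likelihood discrepancy (Wishart form)

$$F_{ML} = \log|\Sigma(\theta)| + \mathrm{tr}\!\left(S\,\Sigma(\theta)^{-1}\right) - \log|S| - p,$$

with $\chi^2 = (n-1)\,F_{ML}$ at the optimum, summed over groups in
multi-group fits. Optimization is BFGS with analytic gradients followed by
Newton polishing to a gradient norm near machine precision — just-identified
models reproduce the closed-form solution to better than $10^{-8}$, which
the acceptance suite verifies against the algebraic loadings
$\lambda_1 = \sqrt{s_{12}s_{13}/s_{23}}$.

Identification fixes factor variances to 1 (a `first_loading` option
exists). Residual variances are unconstrained during optimization so that a
Heywood case (negative residual variance) is *detected and flagged*, never
silently repaired; the genetic-model wrapper (below) is the one place an
automatic constrained refit happens, because that mirrors standard practice
for genetic covariance models.

**Robust corrections.** With `estimator = "ml_robust"` (the default) the
package computes sandwich standard errors and a mean-scaled
(Satorra–Bentler-type) chi-square from the empirical fourth-moment matrix
of the indicators. Fit indices then use the scaled chi-square. The exact
robust variant is a genuine open choice; the mean-scaled statistic was
chosen because it is the common default in applied SEM software and is
testable by calibration (under normal data the scaling factor is near 1).
With missing data the model is fitted by full-information ML over
missingness patterns (the saturated model comes from an EM algorithm);
standard errors are then observed-information and the chi-square is
unscaled — with the <5% MCAR missingness this package targets, the
difference is immaterial, and `missing = "listwise"` exists for checking.

**Fit indices.** CFI, TLI, RMSEA (with a 90% interval from inverting the
noncentral chi-square distribution), SRMR on the correlation metric, and
AIC $= -2\ell + 2q$. With $df = 0$, RMSEA and TLI are reported as `NA`.
`fit_index_block()` is a pure function of $(\chi^2, df, \chi^2_b, df_b, n)$,
so stored indices can always be recomputed bit-identically.

**Model comparison.** Because chi-square difference tests reject trivial
restrictions at large $n$, `compare_models()` judges a nested restriction
*depreciated* when CFI drops by more than 0.01 or RMSEA rises by more than
0.015, and *equivalent* otherwise. The source convention for the CFI rule
is sometimes written with a confusing sign ("$\Delta CFI > -0.01$ indicates
depreciation"); this package implements the standard Cheung–Rensvold
reading: a CFI *decrease* larger than 0.01 is depreciation.

**Invariance ladder.** `invariance_ladder()` fits configural, metric
(equal loadings; factor variances freed in non-reference groups), scalar
(plus equal intercepts; factor means freed in non-reference groups) and
residual (plus equal uniquenesses) models, comparing each level to the
previous. `age_bands()` provides the 51–64 / 65–74 / 75–83 grouping used
for older-adult panels.

**Factor scores** use the regression method,
$\hat f = \Psi \Lambda' \Sigma(\hat\theta)^{-1} (x - \hat\mu)$, with
pattern submatrices for incomplete rows, standardized within sample.

## Genotype processing and polygenic scores

`qc_filter()` applies the three screens in a fixed order — individuals with
missing call rate > 2%, then SNPs with call rate < 98% (computed on the
retained individuals), then SNPs failing an exact Hardy–Weinberg test at
$p < 10^{-4}$. The order is a stated decision: call-rate and HWE statistics
depend on the retained individual set. The HWE test enumerates the
conditional distribution of heterozygote counts exactly, because a
$10^{-4}$ threshold lives in the tail where the chi-square approximation is
unreliable at moderate counts.

`ancestry_pca_select()` implements the two-stage selection: PCA on all
individuals (mean-imputed, variance-standardized dosages; monomorphic SNPs
excluded rather than divided by zero), retention of labelled individuals
within ±1 SD of the mean on PCs 1 and 2, then a second PCA within the
retained sample to produce the top 10 ancestry-specific PCs. Whether the
stage-1 window statistics come from all individuals or the labelled subset
is configurable (`reference`), since the procedure is ambiguous on this
point; the default uses all individuals. No LD pruning is applied before
PCA — fidelity to the stated procedure was preferred over PCA best
practice.

`harmonize_weights()` matches SNPs by id, aligns the effect to the panel's
counted allele, and re-orients every SNP so weights are non-negative
(risk-increasing coding). Strand-ambiguous SNPs are kept by default
(matching a genotyped-array-to-GWAS workflow with no strand inference); a
`drop_palindromic` flag exists. `compute_pgs()` forms
$\text{score}_i = \sum_j w_j\,d_{ij}$ over *all* matched SNPs — no LD
trimming and no p-value threshold anywhere — with missing dosages
mean-imputed at twice the counted-allele frequency (the PLINK convention;
`omit` is available), then z-scored within sample. Matching is by SNP id
only; duplicate ids are dropped with a warning.

## LD-score regression and the genetic factor model

`compute_ld_scores()` computes
$\ell_j = \sum_k r^2_{adj}(j,k)$ over a SNP window, with the small-sample
adjustment $r^2_{adj} = r^2 - (1-r^2)/(n-2)$. `ldsc_univariate()` regresses
per-SNP $\chi^2$ on $N\ell_j/m$ (slope = $h^2$, free intercept);
`ldsc_bivariate()` regresses $z_{1j}z_{2j}$ on $\sqrt{N_1N_2}\,\ell_j/m$,
whose free intercept absorbs correlated estimation error from sample
overlap. Two weighting schemes are available: `"iterated"` ($1/\ell$ on a
first pass, inverse-variance weights recomputed once from its fitted
values, with the predictions floored so a poor first pass cannot give
individual SNPs explosive weights) and `"inverse_ld"` (plain $1/\ell$).
The floor at $\ell \ge 1$ applies to the weights only, never to the
regressor. At desk-scale SNP counts the two schemes trade off
differently: iterated weights de-leverage high-LD SNPs, which is what
identifies the overlap intercept, but carry a small downward slope bias
(weights estimated from the same data), while $1/\ell$ weights leave the
slope unbiased with wider, conservative intervals. `build_genetic_cov()`
therefore also offers `weights = "mixed"` — $1/\ell$ for the diagonal
(heritabilities), iterated for the off-diagonals and intercepts — which
the calibration experiments use.

Standard errors come from a delete-a-block jackknife over contiguous SNP
blocks; `build_genetic_cov()` uses one shared set of blocks for every
element of $S$, so the jackknife covariance $V$ captures cross-element
dependence, and exposes the per-block leave-one-out estimates so derived
quantities (a genetic correlation, say) can be jackknifed directly. Block
counts matter twice over: a jackknife block must span several LD blocks
to be approximately independent, and confidence intervals use
$t_{B-1}$ quantiles. $S$ and $V$ are smoothed to the nearest positive
semi-definite matrix by eigenvalue clipping when needed, with the
perturbation norm recorded.

For nested genetic models the per-model mean-scaled chi-squares are not
monotone under nesting (their scale factors differ), so `compare_gsem()`
implements a scaled *difference* test on the raw quadratic forms — the
DWLS analogue of a Satorra–Bentler scaled difference statistic — and a
Heywood constraint triggered in either model of a comparison pair should
be applied to both (as the calibration experiment does), keeping the pair
nested with a well-defined df difference.

$S$ is estimated on the standardized observed scale throughout; no
liability-scale conversion is attempted (out of scope), which matters only
for interpreting the absolute scale of case/control heritabilities, not
for factor structure.

`fit_gsem()` fits the factor model to $(S, V)$ by diagonally weighted least
squares, $W = \mathrm{diag}(V)^{-1}$, with sandwich standard errors using
the full $V$ and a mean-scaled residual chi-square
$T = df \cdot r'Wr / \mathrm{tr}(UV)$ whose expectation is $df$ under a
correct model. CFI is computed against the independence model on the same
$(S,V)$; AIC follows the $\chi^2 + 2q$ convention of genetic-covariance
SEM software; SRMR is on the correlation metric. When a residual variance
goes negative the model is refitted with that residual fixed to zero and
flagged — the residual-fixed form was chosen over fixing the loading to 1
because the two are equivalent only under unit-variance identification
(the default here), and the residual form is the better-defined constraint.

`latent_snp_weights()` estimates, per SNP, the regression of the latent
factors on the SNP with the measurement model held at its no-SNP estimates:
the implied SNP–trait covariances are $\lambda_{ik} b_k$, so $b$ solves a
small weighted least-squares problem per SNP (one-at-a-time SNP models;
joint re-estimation per SNP is out of scope for tractability and
determinism). The sampling covariance of the per-SNP standardized effects
uses the cross-trait LDSC intercept matrix, so sample overlap propagates
into the latent weights' standard errors. Weights are emitted per factor
and convert losslessly to the scoring weight-table format, so latent PGSs
are computed by `compute_pgs()` exactly like observed-trait PGSs.

## Association models and the power gate

`regress_with_pcs()` is OLS of an outcome on one predictor plus the 10
ancestry PCs, reporting the unstandardized effect, standardized effect,
full-model $R^2$, covariates-only $R^2$, their difference (incremental
$R^2$ — the standard PGS performance metric) and adjusted $R^2$. Both
full-model and incremental $R^2$ appear in every report because "variance
explained" claims are ambiguous between them. No multiple-testing
correction is applied; instead `min_detectable_r2()` provides a power-based
interpretability gate: it solves the noncentral-F power equation for the
detectable $f^2$, converts to $R^2$ and applies the adjusted-$R^2$
correction. All predictor-count configurations are exposed because the
printed gate value in any given study depends on an unstated configuration;
the function is validated against an independent noncentral-F root-finder,
not against any particular published number.

## The synthetic-data generator

`simulate_genotypes()` draws diploid dosages from a Gaussian copula: two
latent standard normals per individual (one per haplotype), equicorrelated
within LD blocks, thresholded at the allele-frequency quantile and summed.
This gives exact control of allele frequencies and approximate control of
LD with trivial sampling. Block boundaries are drawn once per panel (from
the panel's own `meta_seed`, not the draw seed), so block sizes — and hence
LD scores — vary across the panel as in real genomes, and every cohort
simulated from one panel shares the same population structure. The
generator does not attempt realistic human LD maps, imputation, sex
chromosomes or admixture.

`simulate_multitrait_gwas()` draws per-SNP true effects from a latent
genetic factor model (factor-mediated plus trait-specific components, all
SNPs causal at the $1/m$ infinitesimal scale), simulates individual-level
cohorts on a shared genotype pool, and computes per-SNP marginal
regressions. Sample overlap is realized by interval allocation of cohorts
in the pool, so cross-trait LDSC intercepts arise mechanistically rather
than being injected. Cohort sizes default to the 5,000–20,000 range and
SNP counts to 1,200–5,000: LDSC estimands are scale-free, so recovery is
testable at desk scale even though real consortium GWAS are orders of
magnitude larger. All simulated traits are continuous (observed-scale
pipeline; liability conversion out of scope) and missingness is MCAR only.

`simulate_phenotype_panel()` generates indicators as
`intercept(group) + loading x factor + residual`, with group-specific
intercepts and factor scales for planting invariance violations, and
optionally a fixed *nuisance dimension* that no fitted model represents.

**Why the nuisance dimension exists.** An exactly-factor-structured truth
makes the true model's population RMSEA zero, so the RMSEA of a fitted
true model sits at the zero floor while the rival model's RMSEA floats —
their difference is then dominated by one-sided sampling noise and
delta-fit decisions become unstable coin flips. Real questionnaire panels
are never exactly factor-structured: published fits of both one- and
two-factor models to such panels show substantial chi-squares for both.
The default phenotype truth is therefore calibrated so the population
discrepancies of the one- and two-factor models at n = 3002 sit at the
realistic level (population RMSEA roughly 0.047 and 0.041, difference
well inside the 0.015 band), with the two-factor correlation at 0.82.
Under these conditions the split-half pipeline reproducibly prefers the
parsimonious one-factor model.

**The frozen default conditions** (used by tests and the acceptance
script): phenotypic internalizing loadings (0.88, 0.80, 0.63),
externalizing (0.50, 0.42, 0.33), inter-factor correlation 0.82, nuisance
0.8·(0.2, 0.1, −0.25, 0.3, −0.2, 0.1), n = 6003 split 3002/3001; genetic
two-factor truth with standardized loadings 0.70/0.88/0.95 (internalizing)
and 0.81/0.60/0.50/0.79 (externalizing), SNP heritabilities 0.09–0.22,
factor correlation 0.64, fully overlapping cohorts of 12,000 with
environmental correlation 0.5 (the "many consortia, shared samples"
regime); and a single-factor *pleiotropic* genetic truth (standardized
loadings 0.85–0.95) for the latent-PGS experiments.

**What passing tests do and do not show.** The generator produces Gaussian
indicators, block-equicorrelated LD, MCAR missingness and exactly known
truth. Passing recovery tests therefore demonstrates the estimators are
correct and calibrated under their own assumptions at desk scale; they do
not certify behaviour under real LD maps, non-normal phenotypes,
informative missingness, population stratification beyond simple planted
clusters, or consortium-scale sample sizes.

## The pipeline's decision rule

`run_study()` compares the one- and two-factor phenotypic models on the
test half with the delta-criteria and accepts the parsimonious one-factor
model when the two-factor model offers no delta-criteria improvement. The
inter-factor correlation is additionally checked against an alert level
(default 0.80): a correlation above it means the two factors are not
distinct constructs, and the alert is reported alongside the verdict as
corroborating diagnostic. A strict variant requiring the alert *and*
equivalence before choosing the one-factor model is available
(`thresholds$require_alert = TRUE`); under the calibrated default
conditions both rules give the same decision, but the parsimony-first rule
is the default because an equivalence verdict alone already justifies the
simpler model, while the alert estimate carries sampling noise around its
threshold. The holdout half refits only the accepted structure.

## Latent-PGS advantage: when aggregation helps

The latent-weight experiments deserve one honest caveat. A latent-factor
PGS aggregates GWAS noise across traits and so beats every single-trait
PGS when trait-specific genetic variance is small relative to GWAS
sampling noise — the pleiotropic regime, and the regime real consortium
GWAS occupy (residual heritability per SNP is tiny next to $1/N$). At
desk-scale simulation sizes ($m \sim 10^3$, $N \sim 10^4$) a two-factor
truth with large trait-specific residuals puts trait-specific genetic
signal on the same order as sampling noise, and a single excellent
instrument (a trait loading 0.95 on its factor) can match the latent
score. The advantage experiment therefore uses the single-factor
pleiotropic truth, where effects act only through the shared factor —
the mechanism the latent-PGS construction exploits.

## Numerical choices and degenerate inputs

* Optimizer: BFGS (`reltol 1e-14`) plus Newton polishing; non-convergence
  is reported with the gradient norm.
* Non-positive-definite excursions during optimization are handled by a
  smooth penalty pushing back toward the start values.
* Monomorphic SNPs: excluded from PCA standardization; LD scores 0;
  per-cohort monomorphic SNPs give `NA` summary statistics.
* Zero-variance scores (all-zero weights, constant raw scores) are a clean
  error, never NaN.
* `df = 0` models: RMSEA/TLI `NA`; chi-square exactly 0 to optimizer
  tolerance.
* Jackknife blocks: contiguous, shared across all S elements; counts
  configurable, with the block-size-vs-LD-range caveat above.
* All randomness flows through per-call integer seeds; identical inputs
  and seeds give bit-identical outputs (pool genotypes are regenerated
  from per-block seeds when too large to cache).

## Problem sizes used by the calibration experiments

The acceptance experiments run at: 100 random matrices (CFA oracle); 100
replicates × 2,000 individuals (invariance calibration, both null and
0.5-SD shift); 20 replicates × 5,000 SNPs × three cohorts of 10,000
(LDSC); 20 replicates × 3,500 SNPs × seven traits of 12,000 (genetic
factor model); 50 end-to-end replicates at 1,200 SNPs with a 1,500-person
target sample (latent-PGS advantage); and 50 phenotype-only pipeline
replicates at n = 6003. These sizes were chosen so each experiment has
enough replicates for stable rates while a full run stays comfortably
within a desktop session.

## Known limitations

* The robust chi-square scaling is computed for complete-data ML only.
* Interval allocation cannot realize every pairwise overlap matrix (e.g.
  equal partial overlap among many cohorts); the realized overlap matrix
  is returned and a warning raised on mismatch.
* Block-jackknife confidence intervals for LDSC heritabilities slightly
  under-cover at desk scale: with ~500 independent LD units the per-block
  effect mass is mildly heavy-tailed and the slope carries a small
  (~3–5%) downward bias, so measured h² CI coverage sits near 0.85
  rather than 0.95 at the calibration scale (the genetic-correlation
  intervals are fine). Panels with many more, smaller LD blocks restore
  coverage but destroy the high-LD leverage that identifies the overlap
  intercept — 5,000 SNPs cannot satisfy both, which is a scale
  limitation, not an estimator defect (the same estimator is calibrated
  in single-trait isolation checks).
* `min_detectable_r2()` exposes the power-gate computation but does not
  claim to reproduce any particular published gate value, whose predictor
  configuration is typically unstated.
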