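---
title: "Mapping gut microbiome-brain associations with cross-validated ridge RSS ratios"
author: "voxelbiome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping gut microbiome-brain associations with cross-validated ridge RSS ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxelbiome)
```

## The problem

Relating a gut microbial community to brain structure is a massive
multiple-testing problem: hundreds of bacterial families against hundreds of
thousands of MRI voxels would require an infeasible number of pairwise
tests. `voxelbiome` takes the multivariate route: **one** model per voxel
that uses the relative abundances (RA) of *all* bacterial families at once,
followed by a single permutation-based correction across voxels.

For voxel $v$ with per-subject value $y_v$, the full model is a ridge
regression

$$y_v = \alpha + \sum_f \beta_f \ln \mathrm{RA}_f + \gamma_1\,\mathrm{sex} +
\gamma_2\,\mathrm{age} + \gamma_3\,\mathrm{BMI} + \varepsilon,$$

and the association statistic is the cross-validated RSS ratio

$$\mathrm{RSSratio}_v \;=\;
\frac{\mathrm{RSS}_{\text{covariates}}}
     {\mathrm{RSS}_{\text{microbiota + covariates}}},$$

where both residual sums of squares are 10-fold cross-validated: a ratio
above 1 means the microbiota improve *held-out* prediction of that voxel.
Cross-validation is the anti-overfitting device -- adding dozens of
pure-noise regressors cannot systematically push the ratio above 1, because
they do not help out-of-sample.

Ridge regression is used because compositional family tables are
multicollinear by construction; the penalty trades a tolerable downward bias
in the coefficients for stable estimates. The natural-log transform makes
the linear model expressive about *patterns* of abundance: coefficients of
$+1$ and $-1$ for families A and B encode the ratio
$\mathrm{RA}_A/\mathrm{RA}_B$, a coefficient of $2$ encodes
$\mathrm{RA}_A^2$, and so on.

## Preprocessing

* **Flooring.** RAs below $10^{-3}$ are replaced by $10^{-3}$ before the log
  transform, so vanishing abundances cannot produce outlying values near
  $-\infty$. Rows are *not* renormalized afterwards: renormalization would
  perturb exactly the between-family ratios the coefficient patterns encode.
* **Prevalence filter.** A family is retained iff at least 5% of subjects
  have RA strictly above 1%. The boundary is inclusive on the subject
  fraction ("at least 5%") and strict on the abundance (">1%"). The filter
  is applied to the raw table; because the floor only touches values far
  below 1%, the retained set is identical either way.
* **Voxel mask.** A voxel is analyzed iff its mean intensity across subjects
  exceeds 10% of a robust maximum (the 98th percentile of the mean image),
  excluding implausible out-of-brain locations; a user mask overrides this.
* **Standardization.** Design columns are standardized to mean 0, sd 1
  (recorded for back-transformation) so a single penalty is commensurable
  across regressors. Inside cross-validation, standardization is recomputed
  from each training fold only -- no leakage.

## The penalty and what is penalized

The method as published leaves two choices open; both are explicit,
config-visible decisions here:

* **Penalty selection.** The penalty grid is 20 points log-spaced in
  $[10^{-3}, 10^3]$ (standardized scale). Within each training fold the
  penalty is chosen per voxel by **generalized cross-validation (GCV)** on
  that fold's training data. Nested CV would multiply the cost of every
  permutation by the grid size; GCV gives a leak-free per-fold rule at
  negligible cost. The standalone `select_lambda()` offers the classic
  K-fold-CV rule with ties broken toward the larger (more conservative)
  penalty.
* **What carries the penalty.** By default only the microbiota block is
  penalized: the covariates (and intercept) enter both models as an
  unpenalized nuisance, so the covariate-only model is an ordinary
  least-squares fit and the full model is a partial ridge on the
  covariate-residualized log abundances. We initially implemented the
  all-penalized variant (one penalty over families *and* covariates, the
  covariate-only model a ridge of its own) and found it miscalibrated:
  under a global null with predictive covariates the single shared penalty
  cannot shrink the noise families without also shrinking the covariate
  fit, so the full model is systematically handicapped and the null ratio
  median sits near 0.90. With the nuisance unpenalized the null median is
  ~0.99 and planted-signal power is unchanged. The all-penalized variant
  remains available via `penalize_covariates = TRUE`.

```{r null-ratio, eval = FALSE}
co <- simulate_cohort(null_scenario(n_subjects = 133, seed = 1))
s <- assemble_design(co$abundances, co$covariates)
m <- build_voxel_mask(co$stack)
sm <- rss_ratio_map(s, co$stack, m, make_folds(133, seed = 1))
median(sm$ratio[sm$voxels])  # ~0.99: null ratios hover just below 1
```

## Inference

**Freedman-Lane permutations.** To test the microbiota block in the
presence of covariates, the reduced (covariate-only, OLS) model is fitted
per voxel; surrogates are $y^* = Z\hat\gamma + P_b\,\hat\varepsilon$ with
permuted reduced-model residuals, and the *entire* statistic pipeline
(fold-wise standardization, GCV penalty selection, both models) is rerun on
each surrogate. The first permutation is always the identity, so the
observed statistic is counted in its own null and the minimum attainable
p-value is $1/B$ -- 0.004 at the default budget of $B = 250$. With $n \le 7$
subjects the $n!$ permutations are enumerated exhaustively instead of
sampled; at study scale, permutations are sampled uniformly without
enforcing distinctness ($n! \gg B$).

**Staged budget.** Permutation inference is expensive, so the budget is
staged: 50 permutations first, then 200 more where something looks
promising (`extend_inference()`). Each permutation's seed derives from the
master seed and its absolute index, and every surrogate is processed at the
same matrix width, so the staged result is *bit-identical* to a single
250-permutation run. (This matters in practice: optimized BLAS kernels give
slightly different roundings at different matrix widths, which is also why
the subgroup rerun recomputes its full-sample reference at peak-width.)

**TFCE and FWE control.** Family-wise error across voxels is controlled via
the permutation distribution of the mask-wide maximum of the
threshold-free cluster enhancement (TFCE) of the statistic map. TFCE
integrates cluster extent$^E$ $\times$ height$^H$ over all thresholds,
giving cluster-like sensitivity without a cluster-forming threshold.
Decisions, since the method names TFCE but no parameters:

* the enhanced statistic is $s = \max(\mathrm{RSSratio} - 1,\, 0)$ -- the
  null centres ratios near 1 and TFCE requires a nonnegative statistic
  anchored at 0;
* $E = 0.5$, $H = 2$, 26-connectivity, integration step $dh =
  \max(s)/100$ per map -- the de-facto standard volumetric
  parameterization; all exposed in `tfce_params()`.

Uncorrected p-values come from each voxel's own permutation null of the RSS
ratio; FWE p-values from the max-TFCE null. Reporting uses two regimes: the
primary FWE $< 0.05$ threshold, and an exploratory regime (uncorrected $p$
at the minimum attainable level *and* ratio $> 1.33$, i.e. more than a 25%
held-out RSS reduction). Because 0.004 *is* the minimum attainable p at
$B = 250$, the exploratory threshold is applied inclusively.

## Post-hoc analyses

**Family contributions.** At each significant peak the full model is refit
on the complete sample (penalty by GCV) and each family's signed
coefficient is reported on the log-RA scale. Contribution p-values use a
**per-family Freedman-Lane null that reuses the run's permutation set**:
for family $f$ the reduced model contains the covariates plus all *other*
families, so only $f$'s own association is destroyed in its surrogates. A
covariate-only reduced model is not usable here -- destroying *all*
microbiota signal at once changes the GCV shrinkage between observed and
surrogate refits, which demonstrably skews every family's p-value at a true
peak; with the per-family null, a no-signal family's p-values are uniform
even when neighbouring families carry real signal. Significance tiers
(* $p<0.01$, ** $p<0.001$, *** $p<10^{-6}$) below $1/B$ are unreachable at
the default budget.

**Subgroup reruns.** RSS ratios are recomputed at the significant peaks
within a subgroup (e.g. BMI > 25, nonsmokers, no antidepressants) with
freshly assigned folds; subgroups smaller than $2K$ subjects are refused.
The fold seed derivation matches the main run's, so a subgroup equal to the
whole cohort reproduces the full-sample ratios exactly (deltas identically
zero). Deltas scale with the effect size: a strongly planted synthetic
cluster can show much larger subgroup deltas than the modest ratios
(1.3-1.6) typical of real findings.

**Brain-behaviour correlations.** Peak voxel values are correlated
(Pearson) with the clinical scores on pairwise-complete observations --
missing clinical entries are dropped per test, never imputed --
with Benjamini-Hochberg FDR correction across all peak-by-variable tests of
the run, and two flags: FDR $q<0.05$ and nominal $p<0.05$. Correlations are
plain (not partialed on covariates); a partial-correlation variant would be
a small extension behind the same interface.

## The synthetic cohort generator

No real MRI + metagenome data ship with the package, so every statistical
property is exercised on synthetic cohorts with known ground truth
(`scenario()`, `simulate_cohort()`):

* **Abundances** are log-normal intensities closed to the simplex
  (dispersion 0.7 on the log scale; geometric means decaying from ~0.2 to
  ~0.005 across common families), giving heavy-tailed, correlated
  compositions. Families 1 and 2 form a strongly collinear pair (the
  motivating case for ridge), and a configurable fraction of families
  (default 0.3) is generated almost entirely below the $10^{-3}$ floor,
  emulating the long rare tail of real family tables. A Dirichlet
  alternative would also be defensible; the log-normal was chosen for its
  explicit heavy-tail control.
* **Covariates** emulate a middle-aged, predominantly female, high-BMI
  adult cohort: sex ~ Bernoulli(0.69), age ~ Normal(46.7, 10.7) truncated
  to [22, 66] years, BMI ~ Normal(35.3, 10.9) truncated to [19, 64] kg/m².
  Default cohort size is 133.
* **Images** are a brain-like ellipsoid (semi-axes 0.38 of each dimension)
  of baseline intensity 10 plus a uniform covariate effect
  (sex 0.5, age 0.02/yr, BMI 0.03 per kg/m²) and i.i.d. Gaussian voxel
  noise (default sd 1); inside each planted spherical cluster the voxel
  value additionally follows
  $\sum_f \beta_f \ln(\max(\mathrm{RA}_f, 10^{-3}))$. The effect-size scale
  for real microbiota-voxel associations is unknown; scenario defaults are
  calibration choices, not estimates.
* **Clinical scores** (PHQ-9, TMT-A/B, Stroop-CW, Digit Span) are coupled
  to the standardized region mean of the first planted cluster with target
  correlation `clinical_effect` (default 0.3, the order of magnitude of
  reported brain-behaviour correlations), mapped onto each instrument's
  scale, with ~5% missingness to exercise pairwise-complete handling --
  mirroring the two-step logic microbiota → brain → behaviour.

What the generator does **not** emulate: spatial noise correlation and
smoothing, registration error, modality-specific intensity distributions,
sequencing noise in the abundance estimates, and covariate-microbiome
dependence. Passing tests therefore demonstrate the statistical machinery
is correct and calibrated under the stated model, not that effect sizes in
real data will look like the synthetic ones.

## Numerical choices and degenerate inputs

* Ridge solutions use the SVD of the (residualized, scaled) design;
  singular values below $10^{-12}$ of the largest are dropped, which makes
  the $\lambda = 0$ limit the minimum-norm solution (with a warning) rather
  than an error.
* GCV ties and CV-RSS ties select the larger penalty; exactly constant
  outcomes therefore return the largest grid value.
* A voxel with zero full-model CV RSS (possible only on degenerate
  noiseless input) gets ratio $+\infty$ with a warning; 1 if both models
  are exactly zero.
* Fold assignment is balanced (sizes differ by at most 1) and requires
  $n \ge 2K$; folds leaving fewer than 2 training subjects error out.
* All randomness (folds, permutation stream, subgroup folds) derives from
  one master seed via a documented tag + index derivation (`derive_seed()`),
  keeping every derived seed below $2^{31}$.

## Problem sizes used by the test-suite

The packaged validation works at deliberately small scale so the whole
suite runs on a single CPU in minutes: global-null calibration uses 200
cohorts of 40 subjects, 100 families, a 12³ image (~430 in-mask voxels) and
100 permutations (the realized FWE rate must fall in the exact binomial 99%
interval around 0.05, and uncorrected p-values must pass a
Kolmogorov-Smirnov uniformity check at $\alpha = 0.01$); signal recovery
plants one 33-voxel cluster ($\beta = 1$ on two families, noise sd 0.5,
n = 80) and requires Dice $\ge 0.3$ against the truth plus correct top-3
families with correct signs in $\ge 90\%$ of 20 replicates. The same
machinery scales to realistic image sizes by chunking voxels; voxels are
processed independently, and results are identical to sequential
processing.

## Known limitations

* The RSS-ratio statistic has no analytic null; all inference is
  permutation-based, and p-value resolution is limited by the budget
  ($1/B$).
* A single penalty per voxel model means strongly heterogeneous
  family effects share one shrinkage level.
* The family-contribution test is a principled stand-in (the generating
  family-level test behind published significance tiers is typically
  unnamed); its per-family null is exact only up to the ridge shrinkage
  bleed between correlated families.
* Compositional closure means "one family's effect" is never fully
  separable from the rest of the composition; log-RA coefficients should be
  read as pattern weights, not causal effects.
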