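---
title: "Methods: multivariate ADE twin models with rater effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multivariate ADE twin models with rater effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it implements:
the model and its assumptions, the tunable parameters and their defaults, what
the synthetic-data generator does and does not emulate, the numerical choices
inside the estimator, and the known limitations.  Every empirical statement
here is one the test suite or `scripts/acceptance.R` computes.

## The model

The classical twin design decomposes phenotypic (co)variance by contrasting
monozygotic (MZ) pairs, who share all genetic effects, with dizygotic (DZ)
pairs, who share on average half the additive effects (correlation 0.5
between additive factors) and a quarter of the dominance effects (25% of DZ
pairs share both alleles identical by descent, hence a correlation of 0.25
between dominance factors).  When the MZ correlation exceeds twice the DZ
correlation — as it does for childhood inattention/hyperactivity ratings —
the workable three-component model is ADE: additive genetic (A), dominance
(D), and unshared environment (E, which absorbs measurement error).  A, D and
a shared-environment component C are not jointly identified in twin data, so
the package allows ADE or ACE, never ADCE.

For `M` phenotypes per twin, each component covariance matrix is
parameterized by its Cholesky factor, `Sigma_X = Delta_X %*% t(Delta_X)` with
`Delta_X` lower triangular.  This guarantees positive semidefiniteness; the
reported results are never the `Delta` matrices but the derived quantities.
Two measurement features are modelled explicitly:

* **Teacher-rater factor.**  A single latent factor loads (one free loading
  per teacher-rated phenotype, an equality constraint is available) on the
  teacher-rated phenotypes of each twin.  Its cross-twin correlation is fixed
  at 1 for pairs rated by the same teacher and 0 otherwise, yielding four
  covariance groups (MZ/DZ x same/different teacher).  Pairs with no teacher
  ratings at all need no fifth group: FIML marginalizes the teacher
  coordinates away, and the likelihood of the remaining coordinates does not
  depend on the sharing flag.
* **Sex main effects.**  Per-twin means are `intercept + beta_sex * sex`
  (0 = boys, 1 = girls), identical across twins and zygosities.  Sex enters
  the means only; the multivariate model does not moderate variance
  components by sex (the univariate likelihood-ratio machinery for testing
  such moderation is provided separately).

All derived tables standardize by the A+D+E variance, excluding the rater
variance, so heritabilities are "corrected for" rater effects: per phenotype
`a2 = Sigma_A[jj] / tot_j` with `tot_j = Sigma_A[jj] + Sigma_D[jj] +
Sigma_E[jj]`, broad-sense heritability `h2_b = a2 + d2`, component
correlations `corr_X = cov2cor(Sigma_X)`, covariance proportions
`(Sigma_A + Sigma_D) / (Sigma_A + Sigma_D + Sigma_E)` elementwise, and
implied phenotypic correlations either as
`sqrt(h2_i) corr_AD[ij] sqrt(h2_j) + sqrt(e2_i) corr_E[ij] sqrt(e2_j)` or by
normalizing `Sigma_A + Sigma_D + Sigma_E` — the two routes are algebraically
identical and both are implemented and cross-checked to 1e-10 in the tests.
Correlations whose component variance is exactly zero are reported `NA`
(undefined), never 0.

## Preprocessing

Absolute-judgement symptom scales are left-censored and skewed.  The package
implements the shifted Box-Cox map `z = ((y + 1)^lambda + 1) / lambda`; the
trailing `+1/lambda` differs from the textbook `-1/lambda` only by a constant
`2/lambda`, so covariances, correlations and variance components are
identical under either form.  The exponent is estimated by maximizing the
normal profile log-likelihood including the Jacobian term
`(lambda - 1) * sum(log(y + 1))`, by continuous optimization over
`lambda` in `[-6, 3]` with a coarse-grid unimodality guard; the box is a
package choice that comfortably brackets exponents seen for such scales
(roughly -3.6 to -1.1).  The map only requires `y > -1`, and that is the
precondition enforced (raw scores are nonnegative in practice).  After
transformation each phenotype is divided by its *pooled* standard deviation
(all twins, both zygosities together), so the pooled variance is 1 while
sex/zygosity/twin differences in variance are retained — rescaling is purely
a numerical convenience for raw-data ML.

Subscale scores are average item scores; a score is missing when 20% or more
of the items are missing (the boundary counts as missing), and below that
threshold missing items are imputed with the subject's mean over observed
items, which leaves the score equal to the observed-item mean.

## Estimation

Each pair contributes the multivariate-normal log density of its observed
coordinates (mean and covariance subset by row/column deletion) — casewise
full-information maximum likelihood.  The engine evaluates this by grouping
pairs into cells that share (zygosity, teacher-sharing, sex pattern,
missingness pattern); within a cell the mean vector and covariance submatrix
are constant, so the cell contributes
`n [k log 2pi + log|S| + (ybar - mu)' S^{-1} (ybar - mu)] + tr(S^{-1} Sc)`
with `Sc` the centered cross-product matrix precomputed once.  This is
algebraically identical to the casewise sum (the tests verify agreement to
1e-9 at arbitrary parameter values) but costs `O(#cells)` per evaluation
rather than `O(n)`.  Gradients are analytic: the per-cell derivative with
respect to the covariance is `0.5 (n S^{-1} - S^{-1} (n dd' + Sc) S^{-1})`,
accumulated per covariance group and chained through the linear structure of
the group covariance in the component matrices, then through each
component's parameterization (`Delta Delta'`, `lambda lambda'`,
`Lambda Phi Lambda'`, diagonals).  Analytic and finite-difference gradients
agree to 1e-5 in the tests.

Numerical choices:

* **Starting values.** `Delta_E` from the Cholesky of half the pooled
  phenotypic covariance; `Delta_A` from the Cholesky of 0.8 times the MZ
  cross-twin covariance, PSD-projected by eigenvalue clipping (cross-twin
  moment matrices need not be PSD in samples); `Delta_D` small (0.05 on the
  diagonal); rater loadings 0.3; intercepts at observed means.
* **Multi-start.**  `fit_options(n_starts = 5)` by default: the documented
  start plus seeded jittered perturbations, keeping the best optimum.  All
  starts are logged in the fit object.
* **Convergence.**  `nlminb` with relative tolerance 1e-12; a fit is flagged
  converged when the final gradient sup-norm is below
  `fit_options(gradient_tol = 0.05)` (on the standardized data scale a
  gradient this small cannot move any parameter visibly at the third
  decimal; the test suite additionally verifies that no single-parameter
  perturbation of 0.05 increases the likelihood).  Non-convergence is
  reported, never silent; `flattest_directions()` names the parameters in
  the smallest-curvature directions of the Hessian.
* **Sign conventions.**  `Sigma = Delta Delta'` is invariant to flipping a
  column of `Delta` (and `lambda lambda'` to flipping `lambda`), so signs
  are canonicalized post hoc: Cholesky diagonals nonnegative,
  majority-positive loadings.  No boundary constraints are imposed beyond
  the parameterization itself, so a variance component can be *estimated*
  at zero without being fixed there.
* **Degenerate inputs.**  A non-PD observed submatrix yields a large penalty
  (never an exception mid-optimization); `Sigma_E` singular is rejected up
  front; fits on a single zygosity warn that A and D are not separately
  identified.

Robust standard errors are the sandwich `A^{-1} B A^{-1}` with `A` the
observed information (finite differences of the analytic gradient) and `B`
the sum of per-pair score outer products (central differences of the per-pair
log-likelihoods); plain observed-information SEs are reported alongside.
Under correct specification the two agree (within 15% at 4,000 pairs in the
tests); under elliptical heavy tails the sandwich SEs are larger.  The
likelihood-ratio tests are plain LRTs; no attempt is made to reproduce any
particular software's scaling correction for robust ML, and that is
documented rather than approximated.

### Sex-moderation tests

`lrt_sex_moderation()` fits a two-group (boys/girls) univariate ADE model
with sex-specific means in every variant, and compares free versus equated
A/D/E standard deviations (joint 3-df test, plus 1-df per-component tests).
By default opposite-sex DZ pairs are excluded from *both* models: including
them in only one of two models would break the nesting a chi-square LRT
requires.  With `include_opposite_sex = TRUE` they enter both models, the
free model giving them sex-specific within-twin structure and cross-twin
covariance `0.5 a_m a_f + 0.25 d_m d_f` (cross-sex genetic correlation one).
The type-I error of the joint test at the 1% level is verified by a
400-replicate null simulation at 600 same-sex pairs per sex (exact 99%
binomial acceptance interval).

## Factor models

The independent pathway (biometric factor) model gives each selected
component (any of A, D, E) two correlated common factors — one per symptom
dimension, each phenotype assigned to exactly one — while phenotype residuals
keep a free within-twin variance and cross-twin covariances free per
zygosity, absorbing component-specific residual structure.  It is fitted by
the same FIML engine; with one factor the factor-correlation parameter is
dropped (it would otherwise be dead weight and distort likelihood-ratio
degrees of freedom).

The fallback confirmatory fit to a printed genetic correlation matrix needs a
discrepancy function, and the source of such matrices typically does not
state one.  The package offers both normal-theory ML with freely estimated
uniquenesses (`method = "ml"`, the default) and unweighted least squares on
the off-diagonals (`"uls"`).  ML is the default because, on the reference A+D
correlation matrix shipped with the package, it reproduces the published
loading pattern and factor correlation (about 0.8), whereas the global ULS
minimum is a qualitatively different solution (factor correlation about 0.9
with flatter loadings) — a point estimate reproduction argument, made
checkable by the tests rather than asserted.  Heywood solutions (communality
above 1) are flagged but returned.

## The synthetic generator

`simulate_twin_pairs()` is the model run forward: sexes and teacher-sharing
drawn per pair, then the `2M` phenotype vector from the exact group mean and
covariance.  Defaults in `reference_design()` emulate the reference study's
structure: 620 MZ and 973 DZ pairs, 52% girls, 48% of DZ pairs opposite-sex,
57.2% teacher sharing, and blockwise missing-completely-at-random (MCAR)
masking at registry-like rates (one maternal instrument block collected only
in sub-projects and so missing for 69% of pairs jointly; the other maternal
block missing for 30% of twins; the teacher block missing for 56% of pairs
plus 12% of individual twins).  Opposite-sex DZ pairs get the same
covariance structure as same-sex DZ pairs — sex enters means only — matching
the analysis model.  `reference_ade_parameters()` builds generating values
from the published standardized components and correlation matrices (PSD
projection at 1e-6 handles the slight indefiniteness that 3-decimal rounding
induces), with rater loadings solving
`lambda^2 / (1 + lambda^2) = published rater share`.

What the generator does *not* emulate, and hence what passing tests cannot
show about real data: item-level response processes (phenotypes are drawn at
subscale-score level; `apply_raw_scale()` adds censoring/skew only
marginally), age effects, informative (non-MCAR) missingness, contrast
effects between twins, assortative mating, sex-moderated variance
components, and any non-normality of the latent scale beyond what the
raw-scale map imposes.  MCAR was chosen deliberately: it keeps FIML unbiased
so that recovery tests isolate the estimator.

## Problem sizes used in the checks

The recovery check fits `M = 4` phenotypes (the four hyperactivity measures,
two teacher-rated with a rater factor, 57.2% sharing) at 2,000 MZ + 2,000 DZ
pairs with MCAR missingness of 10% per twin on the maternal block and 25% on
the teacher block — rates milder than the registry's, chosen so the check
informs about the estimator rather than about missingness.  The `M = 8`
version of the same check is a scaled-up run of the identical code path.
The LRT calibration uses 400 replicates of 600 same-sex pairs per sex; the
independent-pathway recovery uses 3,000 + 3,000 pairs with two factors of
two indicators each.

## Known limitations

* **The a²/d² split is weakly identified.**  The broad-sense sum `a² + d²`
  and `e²` are recovered tightly (within ±0.02 at the 4,000-pair design in
  the acceptance run), but the likelihood is nearly flat along the direction
  that trades `a²` against `d²`: at that design the maximum-likelihood
  estimates of `a²` and `d²` individually can deviate from truth by 0.2
  while the fitted likelihood exceeds the generating parameters' likelihood.
  This mirrors the large standard errors such studies report for `a²` and
  `d²` next to small ones for `h²_b`.  A delta-method check on the
  univariate model gives `SE(a2_hat) ≈ sqrt(16 var(r_DZ) + var(r_MZ)) ≈
  0.08` at 2,000 + 2,000 pairs.  Conclusions should be drawn from `h²_b`,
  the A+D correlation matrix and the covariance proportions, not from the
  split.
* **Normal-theory likelihood.**  Box-Cox transformation makes the data
  distributionally more suitable but not normal; robust SEs mitigate, and
  liability-threshold/ordinal modelling is out of scope.
* **No contrast (reciprocal sibling-interaction) paths, no sex-moderated
  multivariate variance components, no common pathway model.**
* **The fallback CFA has no standard errors or fit measure** — point
  estimates on a correlation matrix treated as data.
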