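---
title: "Additive stand basal area systems: models, estimators and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Additive stand basal area systems: models, estimators and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(additivesba)
```

This vignette is the package's own account of the science it implements:
the model families, the two additive estimators, the evaluation machinery,
the synthetic-plot generator, and the design decisions taken where the
design was genuinely open.

## Model families

Stand basal area (SBA, m²·ha⁻¹) is modelled per stratum — two species
strata P and B (an aspen–birch mixture is the motivating system) and the
stand total — as a nonlinear function of three stand covariates: site
index `si` (mean dominant height, m), age at breast height `adbh` (years,
from increment cores), and the Reineke stand density index
`sdi` = N·(D₀/D_g)^(−1.605) with reference diameter D₀ = 20 cm
(`reineke_sdi()`).

Three base growth forms in the time variable t = ADBH:

| id | expression |
|---|---|
| `korf` | b₀·exp(−b₁·t^(−b₂)) |
| `schumacher` | b₀·exp(−b₁/t) |
| `richards` | b₀·(1 − exp(−b₁·t))^(b₂) |

and six covariate extensions:

| id | expression |
|---|---|
| `M1` | b₀·SI^(b₁)·exp(−b₂/ADBH)·SDI^(b₃) |
| `M2` | as M1 with SDI/1000 |
| `M3` | exp(b₀ + b₁/ADBH)·SDI^(b₂ + b₄/ADBH)·SI^(b₃ + b₅/ADBH) |
| `M4` | as M3 with SDI/1000 |
| `M5` | b₀·SI^(b₁)·(1 − exp(−b₂·SDI^(b₃)·ADBH))^(b₄) |
| `M6` | as M5 with SDI/1000 |

Two notational choices deserve a note because published flattened
renderings of these forms are ambiguous:

* **M5/M6 parenthesisation.** We place the density-dependent rate
  `b₂·(SDI/1000)^(b₃)·ADBH` inside the exponential and keep `b₄` as the
  outer Richards shape exponent, matching the Richards base skeleton
  (rate inside, shape outside). The choice was cross-checked numerically:
  with the published M6 coefficient sets for the P stratum, this grouping
  predicts ≈ 13 m²·ha⁻¹ at the mean published covariates — consistent with
  the reported mean species SBA of 12.9 — whereas the alternative
  groupings are off by far more than any plausible fit error.
* **SDI scaling.** Forms M2/M4/M6 divide SDI by exactly 1000 (a
  dimensionless convention). The unscaled SDI is always stored and passed;
  scaling happens inside the predictor. The exact equivalence
  `M2(b₀·1000^(b₃), …) = M1(b₀, …)` is asserted in the tests.

`sba_eval()` computes power products in log space and *declines* —
raising a classed error carrying the offending covariate rows — when the
log prediction exceeds 700 in magnitude or a Richards bracket would be
negative, instead of clamping. Fitting code converts such errors into
large penalty residuals, so the optimizer backs away from invalid regions
without silently saturating. A zero bracket with positive shape is the
legitimate limit 0, not an error. Species equations use the stratum's own
(species-partial) covariates by default; a column mapping lets users
supply whole-stand SDI instead if their data are recorded that way.

## Equation-wise NLS

`sba_nls()` minimises the residual sum of squares with the Levenberg–
Marquardt algorithm (`minpack.lm::nls.lm`), with:

* **positivity by log-reparameterisation** for the leading scale b₀ and
  the Richards rate parameters — never by clamping; all other parameters
  are unbounded (published extended-Schumacher fits include negative
  estimates, so sign constraints would be wrong);
* **multi-start initialisation**: the first start is the published
  reference coefficient set for the matching form (or a data-driven
  heuristic for base forms); subsequent starts perturb b₀ by up to one
  order of magnitude and the rest by ±50% (5 starts by default, seeded,
  with the caller's RNG stream restored);
* convergence at relative SSE change 1e-10, at most 500 iterations per
  start; the best converged start by SSE wins;
* standard errors from s²(JᵀJ)⁻¹, s² = SSE/(n−p), with the Jacobian by
  central finite differences on the working (log) scale and the delta
  method back to the coefficient scale. When SSE ≈ 0 (noiseless data) SEs
  are reported as 0 with a `se_degenerate` flag rather than NaN. A
  singular JᵀJ is handled by a Moore–Penrose pseudo-inverse that
  truncates only numerically exact null directions (tolerance 1e-12
  relative to the leading eigenvalue), so *weakly* identified directions
  keep their honest, possibly enormous, variances; the `rank_deficient`
  flag records the truncation.

`sba_rank()` fits a candidate list and orders by descending adjusted R²,
ties by ascending RMSE then ascending parameter count; non-converged
candidates are listed last.

## The AP system

`sba_ap()` estimates the proportional-adjustment system in two stages:
the total equation alone contains the total parameters and the two share
equations alone contain the species parameters, so the stages are
separable. Stage 1 is an ordinary `sba_nls()` fit of the total. Stage 2
estimates both species' parameters *jointly* — the share weight
w = f_P/(f_P + f_B) couples them — by minimising the stacked, equally
weighted SSE of the two species residual vectors, with the stage-1
prediction standing in for the total. A `simultaneous = TRUE` flag
instead stacks all three residual vectors and fits every parameter at
once, for users who prefer the single-objective variant; the default
matches the separable equation structure and keeps the total model
identical to its NLS fit.

One structural fact matters for interpretation: the share weights are
invariant to rescaling f_P and f_B by a common constant, so the joint
scale of the species equations is not identified. We impose no
normalisation (published AP systems report a free leading scale for both
species); the optimizer's damping keeps the estimate near its start along
the exact null direction, the pseudo-inverse SEs flag the deficiency, and
the invariance itself is asserted as a property test.

## The NSUR system

In field data the observed total is the arithmetic sum of the species
observations, so the three-equation error vector is linearly dependent
(ε_t = ε_P + ε_B) and its 3×3 covariance is singular. `sba_nsur()`
therefore estimates the two species equations under a 2×2 cross-equation
covariance Σ and treats the total structurally as the component sum — the
standard resolution for additive component–total systems. For data whose
total is measured independently, `include_total = TRUE` adds the third
equation with a ridge-stabilised covariance (ridge fraction at least
1e-4 of the mean diagonal).

Estimation is iterated feasible GLS: (i) equation-wise NLS starts;
(ii) Σ̂ = RᵀR/n from the species residual matrix (divisor n, not n−p —
simpler and consistent); (iii) joint minimisation of Σᵢ rᵢᵀΣ̂⁻¹rᵢ via
Cholesky whitening of the residual pairs; (iv) re-estimate Σ̂ and repeat
until the maximum relative parameter change drops below 1e-8 or 50 outer
iterations. The generalized objective at frozen Σ̂ is recorded per
iteration (its within-step monotonicity is a test). Standard errors come
from the inverse GLS information (J_wᵀJ_w)⁻¹ of the whitened system.
With Σ̂ forced to the identity and one outer iteration the procedure is
exactly stacked ordinary least squares, which (with no shared parameters)
equals the equation-wise fits — the degeneracy check in the tests.
`efficiency_gain()` tabulates per-parameter SE ratios NSUR/NLS; under
cross-correlated errors the ratios drop below one.

## Evaluation

`sba_metrics()` implements MAE, MPE, RMSE, R² and adjusted R² literally:
MPE is the aggregate relative absolute error Σ|e|/Σy × 100. Published
tables in this literature often print MPE as a proportion (e.g. 0.069);
the package computes the percent form of the defining formula, and every
percent-*change* comparison is scale invariant, so the choice does not
affect comparisons. Degenerate inputs (zero observed total, zero response
variance) yield `NA` metrics with flags rather than errors.

`percent_change(before, after)` reports (before−after)/before × 100 —
positive = the statistic decreased. Recomputing the published
total-stratum comparison table reproduces all six printed error-metric
changes (AP vs NLS: 31.98/31.88/34.12%; NSUR vs NLS: 64.48/36.23/64.75%).
The corresponding R² improvement computes to 2.44% where 2.24% was
printed — a suspected transcription slip in the source table, which the
package reports as computed.

`sba_cv()` performs k-fold cross-validation with a seeded shuffle and
contiguous blocks (fold sizes differing by at most one; 58 plots at
k = 10 gives eight folds of 6 and two of 5), no stratification. Re-fits
start from the full-data estimates; the per-stratum parameter count of
the refitted equation is used for adjusted metrics. Failed folds are
reported and pooled metrics computed on the remaining out-of-fold
predictions with a flag.

## The synthetic generator

`sba_simulate()` stands in for the study's 58 undeposited field plots.
Species covariates are exact truncated normals (inverse-CDF sampling)
with the published per-species mean/SD/min/max; SI, ADBH and SDI are
drawn independently because no cross-covariate correlations are
published (a hook for a correlation matrix exists for sensitivity work).
Stand-level covariates for the total equation are derived from the
species draws — SI and ADBH as arithmetic means, SDI as the species sum;
density indices are approximately additive, and the published stand SDI
mean (698.3) is indeed close to the species sum (711.9). Species
responses are the generating surfaces plus correlated bivariate Gaussian
errors; error pairs that would produce a non-positive SBA are redrawn
(rejection with a 100-attempt budget, so the error distribution is not
truncation-biased at the boundary), and the total is the exact component
sum. Defaults: the published NSUR coefficient sets (Richards M6 for P,
Korf M1 for B); σ_P = 0.63 and σ_B = 0.41 taken from the published
species RMSEs and cross-species error correlation ρ = 0.5 — documented
stand-ins, since neither is published for the study data. Generation is
bit-identical under a fixed (config, seed).

A second generating structure, `structure = "proportional"`, draws
species observations around model-based shares of a total-model surface.
This is the data-generating process under which the AP estimator is
correctly specified, and it is what the AP recovery experiments use (with
the published AP coefficient sets, including the total equation).

What the generator does *not* emulate: spatial structure, repeated
measurements over time, covariate measurement error, non-Gaussian or
heteroscedastic residuals, and cross-covariate correlation. Passing
recovery tests on these data therefore demonstrate estimator correctness
under the stated model, not robustness to real-data violations of it.

## Identifiability of the Richards M6 coefficients

A finding that shapes the recovery experiments: at the published
coefficient scales, the M6 rate term x = b₂·(SDI/1000)^(b₃)·ADBH
evaluates to ~3e-5…3e-3 across the calibrated covariate range, so
1 − exp(−x) ≈ x and the model degenerates to
(b₀·b₂^(b₄))·SI^(b₁)·(SDI/1000)^(b₃·b₄)·ADBH^(b₄). Only the products
b₀·b₂^(b₄) and b₃·b₄ (plus b₁ and b₄) are statistically identified; the
(b₀, b₂) split lies on an essentially exact likelihood ridge, along which
estimates can wander orders of magnitude with no fit penalty, at any
sample size. Monte-Carlo recovery (`sba_recovery_study()`) reflects this
honestly: the identified product is recovered to ~2% (median) at n = 400,
every identified coefficient is covered by ±3 SE at ≈ nominal rates, but
per-coefficient coverage of b₀ and b₂ individually is poor and no SE
recipe can repair it. The package reports the per-coefficient hit rates
and the identified-product series so users can see exactly which
directions the data determine. The same caution applies to interpreting
published M6 coefficient tables: b₀ and b₂ should be read jointly, not
separately.

## Problem sizes and numerical choices

The shipped tests run the recovery studies at 100 replicates of n = 400
plots, the Monte-Carlo NLS coverage at 200 replicates of n = 500, the
additivity property at 1000 random systems, and the distributional checks
at n = 2000–5000 — sizes chosen so each check has clear statistical power
while the full suite completes in well under a minute. Fits inside
replicate loops start from the generating values (the documented default
initialisation is centred on the published sets) with a single start.
Other numerics: finite-difference step 1e-6·max(|θ|, 1); LM tolerances
ftol = 1e-10, ptol = 1e-12; FGLS tolerance 1e-8 on relative parameter
change; pseudo-inverse truncation 1e-12 of the leading eigenvalue;
plot-table additivity validated at 1e-6 absolute; round-trip text I/O at
17 significant digits.

## Known limitations

* The AP estimator is binary (two species); the data model anticipates
  more strata but the share system here is two-equation.
* No mixed-effects or heteroscedasticity machinery: within-equation error
  variance is constant by assumption.
* The M6 identifiability ridge above means species-P coefficient tables
  (from any source) are only jointly interpretable.
* Climate covariates are out of scope.
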