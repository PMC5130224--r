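---
title: "Spatiotemporal latent Gaussian models of county-level insecticide use"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatiotemporal latent Gaussian models of county-level insecticide use}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Simplified agricultural landscapes — counties where harvested cropland
dominates the land cover — are expected to favour crop pests over their
natural enemies, and so to drive up insecticide use. Testing that chain at
a continental scale means regressing *relative insecticide use* (the
proportion of a county's harvested cropland treated with insecticide at
least once in a season, a value in $[0,1]$) on *landscape simplification*
(the proportion of county land in harvested cropland) across roughly 3,000
counties and four quinquennial censuses, while crop mix, farm economics,
climate, and — crucially — unexplained spatial and temporal structure all
compete to explain the same variation.

`insectscape` implements that analysis as a tested pipeline: panel
preprocessing, growing-degree-day computation, six competing Bayesian
latent Gaussian models, MCMC inference with sparse precision algebra, DIC
comparison, residual-variogram and PIT diagnostics, and effect reporting.
A synthetic county-lattice generator reproduces the statistical structure
of the panel so every stage is testable without the census data.

## The model family

All six models share the observation model

$$y_{it} \sim \mathrm{N}(\mu_{it}, \sigma^2), \qquad
  \mu_{it} = \beta_0 + \sum_{m=1}^{7} \beta_m x_{mit} + \sum_l f_l(z_{lit}),$$

with identity link. The seven covariates, in the package's canonical
order and native units (chosen so printed slopes apply directly):

| covariate  | meaning                                             | unit |
|------------|-----------------------------------------------------|------|
| `x_corn`   | share of harvested cropland in corn grain/silage    | proportion |
| `x_cov`    | share in cotton, orchards, vegetables               | proportion |
| `x_sw`     | share in soybean and wheat                          | proportion |
| `x_income` | net farm income per harvested hectare               | thousand USD/ha |
| `x_size`   | harvested cropland per operator                     | km² |
| `x_gdd`    | cumulative annual growing degree days               | thousands |
| `x_crop`   | county land in harvested cropland (simplification)  | proportion |

Covariates (never the response) are centred at their grand means. Year
enters models 2–6 as a centred continuous covariate in calendar years
(1997/2002/2007/2012 → −7.5/−2.5/+2.5/+7.5), so the year slope is a
per-year change.

The models differ in the latent part $\sum_l f_l$:

1. **Model 1** — none: a Gaussian GLM.
2. **Model 2** — adds state (factor, reference coding) and year fixed
   effects.
3. **Model 3** — adds state×cropland, year×cropland and
   state×year×cropland interactions (a fixed-effect probe of
   non-stationarity).
4. **Model 4** — exchangeable (iid) random intercepts per county and per
   year.
5. **Model 5** — Model 4 plus a *spatially varying coefficient*: a random
   slope on `x_crop` over county×year with an intrinsic CAR (Besag)
   structure across counties evolving as an AR1 process across years.
6. **Model 6** — Model 4 plus a CAR-within-AR1 structured random
   *intercept*.

Priors follow the classical defaults for this model class: flat intercept
(Normal with precision 0), Normal(0, precision 0.001) fixed effects,
Gamma(1, 0.00005) on every precision (the log-gamma prior on the log
precision), and Normal(0, precision 0.15) on the transformed AR1
correlation $\log((1+\rho)/(1-\rho))$ — the transformation is stated
explicitly here because the untransformed scale is sometimes quoted
ambiguously.

### The separable space-time precision

The CAR-within-AR1 blocks have precision
$\tau\, R(\rho) \otimes (D - W)$, where $R(\rho)$ is the tridiagonal
precision of a stationary unit-variance AR1 over the years and $D - W$ is
the unscaled Besag structure matrix (degree minus adjacency) of the county
graph. The structure matrix is left unscaled by default, matching the
historical default behaviour of this model class; `build_icar_structure(
scale = TRUE)` enables generalized-variance rescaling. The intrinsic prior
is improper — constant shifts within each connected component cost
nothing — so the package imposes sum-to-zero constraints over the counties
of each component, within each year.

## Inference: blocked Gibbs with sparse precision algebra

Posterior sampling uses a three-part sweep:

* a **joint draw of every Gaussian quantity** (all fixed effects and all
  latent blocks at once) from its Gaussian full conditional, via sparse
  Cholesky factorization (CHOLMOD, through `Matrix`) of the joint
  precision with a symbolic analysis reused across iterations;
  constraints are imposed exactly by conditioning-by-kriging;
* **conjugate Gamma draws** for the error precision and each block
  precision;
* **random-walk Metropolis** on each transformed AR1 correlation, with
  the proposal scale adapted toward 0.44 acceptance during burn-in only
  (so the chain after burn-in is a fixed-kernel Markov chain).

Drawing jointly rather than block-by-block matters: the structured
intercept field and the fixed effects are strongly dependent a
posteriori, and a joint draw makes the fixed-effect subchain mix almost
as well as independent sampling.

Two numerical details deserve note. First, the joint precision of a model
with a flat intercept prior and an intrinsic space-time block is exactly
singular along one direction (a constant added to the intercept and
subtracted from the field). The sampler adds the outer products of the
year-one component-sum constraint rows to the precision: on the
constrained subspace this term is identically zero, so the constrained
draw is exact, while off the subspace it restores positive definiteness.
Second, the default chain length is 10,000 iterations with 2,000 burn-in
and thinning 5; the replicate experiments in the tests and the acceptance
script use 500-iteration chains with 150 burn-in, which the joint-draw
design makes adequate for posterior means and 95% interval endpoints of
fixed effects (the problem sizes used there are stated below).

With the error variance held fixed and no latent blocks, the posterior of
the fixed effects is exactly Gaussian; the test suite uses this
(`sampler_config(fix_sigma2 =)`) to check the sampler against dense
closed-form algebra to Monte-Carlo accuracy.

## Model comparison and diagnostics

* **DIC**: deviance is $-2\log \mathrm{N}(y \mid \mu, \sigma^2)$;
  $p_D$ = mean deviance minus deviance at the posterior means of
  $\mu_{it}$ and $\sigma^2$; DIC = mean deviance + $p_D$. $p_D$ can be
  negative in pathological fits and is reported, not clamped. ΔDIC is the
  difference from the lowest-DIC model.
* **Residuals** are posterior-predictive means minus observations (note
  the sign convention).
* **Variograms**: method-of-moments semivariances of one year's
  residuals, equal-width bins up to half the maximum pairwise centroid
  distance (both configurable), Euclidean distances on planar
  coordinates in km. A Matérn curve is fitted by weighted least squares
  (Cressie weights, pair counts over squared semivariance) over nugget,
  partial sill and range, smoothness selected from {0.5, 1.5, 2.5}. The
  range is confined to the sampled distance domain (first to last
  non-empty bin centre): below it a partial sill is indistinguishable
  from a nugget, above it the sill describes structure the data never
  express, and either way the nugget/sill split would be arbitrary for
  near-flat variograms. The binning and smoothness handling are
  this package's documented choices, not reproductions of any particular
  source.
* **PIT**: the package computes the conditional (in-sample)
  posterior-predictive transform, $\mathrm{PIT}_i = \mathbb{E}\,
  \Phi((y_i - \mu_i)/\sigma)$ over posterior draws — not the
  leave-one-out variant some packages report. For flexible models the
  conditional PIT concentrates toward 0.5 on the fitted data even when
  the model is correct; calibration checks therefore use
  `replicate_pit()`, which scores replicate data drawn from the fitted
  posterior predictive (exactly uniform when the machinery is correct)
  and emits this note in its documentation.

## The synthetic-data generator

`simulate_panel()` emulates the analysis panel's statistical structure on
a rook-adjacency lattice (default 20×20, states as 5×5 blocks, four
census years):

* **Covariates** are smooth Gaussian fields: intrinsic CAR draws with
  small iid jitter, persistent across years (year-specific perturbations
  with weight 0.3), pushed through transforms into realistic ranges —
  a shared multinomial-logistic map for the three crop shares (so their
  sum stays below 1), affine/log-linear maps putting income at a mean of
  0.61 thousand USD/ha (negative values possible, as in the census),
  farm size at 1.196 km², GDD within roughly 0.5–6 thousand degree-days,
  and cropland proportion near 0.29 — means matching the panel's printed
  descriptive statistics.
* **The response** follows the model equation with fixed effects at the
  fitted space-time model's published posterior means (corn 0.398,
  cotton/orchards/vegetables 0.605, soy/wheat 0.041, income 0.004, size
  0.012, GDD 0.030, cropland 0.050, year 0.005, intercept 0.265),
  σ = 0.054, AR1 correlation 0.708, and random-effect scale parameters
  taken from the fitted SD column (0.005 county, 0.008 year, 0.150
  space-time, entered as precisions $1/\mathrm{sd}^2$ of the unscaled
  intrinsic structure). The `generative_model` switch selects which
  latent blocks are active.
* **Censoring** masks each covariate entry independently with
  probability 0.05, standing in for census anonymity suppression (no
  suppression rate is published; 0.05 is a fixed, plausible choice).
* Intrinsic CAR fields are drawn exactly on the sum-to-zero subspace via
  the spectral basis of the structure matrix; the space-time field uses
  the Kronecker construction (AR1 Cholesky × spatial spectral basis), so
  its covariance is the pseudo-inverse of the model's precision — a
  property the tests verify empirically on a 3×3×3 lattice.

What the generator does *not* emulate: real county geography and
adjacency irregularity, census sampling design, crop-price dynamics,
non-Gaussian features of the response (real proportions are censored at 0
and 1), and systematic rather than random suppression. Passing recovery
tests on this generator therefore demonstrates the correctness of the
machinery under the model's own assumptions, not robustness to their
violation.

## Replicate experiments and problem sizes

The tests and `scripts/acceptance.R` run three experiments, all on the
20×20 lattice × 4 years (≈1,600 county-years after filtering), chosen as
the largest size at which 100 replicate fits remain comfortable on one
core:

* **Recovery**: 100 replicates simulated under the space-time model at
  the defaults, Model 6 refitted to each; the 95% credible interval for
  the cropland slope (truth 0.050) should cover at a near-nominal rate
  (≥ 90/100) with absolute bias below 0.01. The full preprocessing
  pipeline (censoring, imputation, filtering, centring) runs inside the
  loop, so the experiment also absorbs the small attenuation from
  imputing censored covariates.
* **Model selection**: on 20 of those replicates, Models 1, 4 and 6 are
  fitted and DIC should order them 6 < 4 < 1 (the generating model
  winning) in at least 95% of replicates.
* **Diagnostics**: on the same 20 replicates, the Matérn
  partial-sill/nugget ratio of final-year residual variograms should be
  larger for Model 1 than for Model 6 (Model 1 leaves the spatial field
  in its residuals; Model 6 absorbs it), and the predictive-replicate
  PIT of the Model 6 fit should pass a 20-bin chi-square uniformity
  check, each in at least 90% of replicates.

## Design choices on genuinely open points

* **Censored-value imputation** fills each withheld entry with the
  county's mean of that field over the observed censuses (zero when no
  year is observed). Because fields are imputed independently, a
  county-year whose observed crop shares were large can end up with
  imputed shares summing slightly above one; the rule is kept total as
  published and such rows are reported with a warning rather than
  altered.
* **The 3% cropland filter** is applied at the county level (a county
  whose mean cropland proportion across censuses falls below 0.03 is
  dropped from all years): the rule as published removes *counties*, not
  county-years. `scope = "record"` switches to per-record filtering.
* **Standardized coefficients** are slope × SD(covariate), *not* further
  divided by SD(response). The published raw/standardized pairs are
  consistent with this convention (e.g. a GDD slope of 0.030 against a
  standardized value of 0.027 implies SD(GDD) ≈ 0.9 thousand
  degree-days; dividing by SD(y) ≈ 0.2 would have produced values about
  five times larger than printed). `scale_by_response_sd = TRUE`
  switches convention.
* **Rounding of effect translations** is half-away-from-zero to two
  decimals, the convention matching the printed values (0.075 → 0.08).
* **GDD clamping** is applied to the inputs before averaging (the
  published wording sets T_min/T_max to the bounds), and the zero floor
  to the daily value during summation. Temperatures are °C only.
* **Isolated counties** (no neighbours after filtering) form their own
  graph component; the sum-to-zero constraint pins their intrinsic
  effect to zero, so they are carried by the exchangeable county
  intercept — no special-casing required.
* **Year fixed effects in Models 2–3** are centred like every other
  covariate, for consistency with the continuous covariates.
* **Negative incomes** are kept as-is (no winsorizing); incomes are
  nominal, not inflation-adjusted.

## Known limitations

* Inference is MCMC rather than the integrated nested Laplace
  approximation commonly used for this model class; agreement is
  validated against closed-form conjugate oracles and parameter-recovery
  experiments, not against any external package's numerical output.
* The Gaussian likelihood can place predictions outside $[0,1]$; the
  package follows the model as published and does not truncate.
* Fitted DIC values, posterior tables and ρ estimates for the real panel
  depend on the full census data and are not reproducible from synthetic
  lattices; the package's experiments target the *qualitative* published
  patterns (DIC ordering, variogram contrast) and the arithmetic of the
  published tables.
* No proper-CAR, Leroux, or Matérn-SPDE latent alternatives; Gaussian
  likelihood only; no cartographic rendering (residual and SVC tables
  are emitted for external mapping tools).
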