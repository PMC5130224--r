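# insectscape

County-level spatiotemporal analysis of agricultural insecticide use.

Simplified agricultural landscapes — counties dominated by harvested
cropland — are expected to favour crop pests over their natural enemies
and so to increase insecticide use. `insectscape` implements the
county-year panel analysis behind that question for R users: it models
*relative insecticide use* (the proportion of a county's harvested
cropland treated with insecticide, in [0, 1]) as a function of crop
composition, farm economics, growing degree days, and *landscape
simplification* (the proportion of county land in harvested cropland),
while accounting for spatial and temporal autocorrelation with
structured random effects. It is written for spatial
ecologists/biostatisticians who want the full pipeline — preprocessing,
model fitting, model comparison, diagnostics, reporting — as tested,
reusable functions.

## The models

Six Bayesian latent Gaussian models of increasing structure, all of the
form

    y_it ~ N(mu_it, sigma^2)
    mu_it = beta_0 + sum_m beta_m x_mit + sum_l f_l(z_lit)

for county *i*, census year *t* (1997, 2002, 2007, 2012), with seven
fixed-effect covariates. The latent terms `f_l` distinguish the models:
none (Model 1); state and year fixed effects (Model 2); plus
state/year × cropland interactions (Model 3); exchangeable county and
year random intercepts (Model 4); plus a CAR-within-AR1 spatially
varying slope on cropland (Model 5, an SVC model); or plus a
CAR-within-AR1 structured random intercept (Model 6). The space-time
blocks use a separable precision — Kronecker product of a stationary
AR1 precision over years and an intrinsic CAR (Besag) structure over
the county adjacency graph — with sum-to-zero constraints per graph
component and year.

Inference is blocked Gibbs sampling with sparse-precision linear
algebra (CHOLMOD via `Matrix`): one joint Gaussian draw for all fixed
effects and latent blocks, conjugate Gamma draws for precisions, and
adaptive random-walk Metropolis for AR1 correlations. Models are
compared by DIC; adequacy is judged by PIT histograms and empirical
variograms of residuals with Matérn fits. A synthetic county-lattice
generator reproduces the panel's statistical structure (spatially
smooth covariates, censored entries, the latent-Gaussian response) so
the whole pipeline runs and is tested without any external data.

## Worked example

The `analysis/` scripts run the study end-to-end on a synthetic 20×20
county lattice (400 counties × 4 years, censored covariates, response
generated under Model 6 at the published posterior means):

```sh
Rscript analysis/01_simulate.R      # panel + adjacency + centroids CSVs
Rscript analysis/02_preprocess.R    # impute, 3% cropland filter, centre
Rscript analysis/03_fit_models.R    # fit Models 1-6, DIC table
Rscript analysis/04_diagnostics.R   # variograms, PIT, residual tables
Rscript analysis/05_report.R        # effect translations, SVC table
```

Step 2 reports the preprocessing trail (this run: 511 censored entries
imputed, 9 of 400 counties dropped by the 3% cropland filter, covariate
grand means stored at centring — e.g. cropland proportion 0.333, income
0.609 thousand USD/ha). Step 3 prints the model comparison:

    model 1: DIC   -1860.8  pD     8.9
    model 2: DIC   -2140.5  pD    25.0
    model 3: DIC   -2180.4  pD    55.5
    model 4: DIC   -2374.9  pD   282.4
    model 5: DIC   -2526.3  pD   404.5
    model 6: DIC   -3950.7  pD   943.9

DIC falls monotonically from the plain GLM to the space-time model: the
generating model (Model 6) wins by a wide margin, and only its
residuals lose their spatial structure — step 4's final-year variogram
partial-sill/nugget ratios are 2.5 for Model 1 against ~10⁻⁸ for
Model 6, while Model 6's predictive-replicate PIT chi-squares (20.5,
11.3, 19.6, 13.8, 15.3 on 19 df) sit comfortably below the 0.99
reference of 36.2. Step 5 translates the best model's slopes onto the
response scale:

    x_corn  0.40 -> 0.80 : +0.15
    x_cov   0.10 -> 0.30 : +0.09
    x_crop  0.20 -> 0.80 : +0.03
    year    0.00 -> 15.00 : +0.07

i.e. moving a county from 40% to 80% cropland in corn raises expected
relative insecticide use by 0.15 (truth used in the simulation: 0.16),
and a 20→80% increase in landscape simplification adds 0.03 — the
moderate positive association the analysis is designed to isolate.
Standardized coefficients (slope × covariate SD) put the crop
composition variables first (corn 0.048), climate next (GDD 0.029), and
simplification in the intermediate group (0.010).

## Package layout

| where | what |
|---|---|
| `R/panel.R` | panel container, readers/writers, imputation, filtering, centring, adjacency |
| `R/gdd.R` | growing-degree-day computation from monthly normals |
| `R/simulate.R` | synthetic lattice panels (covariates, response, censoring) |
| `R/models.R` | model specs, design matrices, ICAR/AR1/Kronecker precision builders |
| `R/fit.R` | the Gibbs sampler, DIC, PIT, posterior summaries |
| `R/diagnostics.R` | residuals, variograms, Matérn fits, PIT uniformity |
| `R/reporting.R` | effect translations, standardized/SVC coefficients, comparison tables |
| `vignettes/` | the methods vignette (model, priors, design choices, limitations) |
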