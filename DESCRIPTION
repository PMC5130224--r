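Package: insectscape
Title: Spatiotemporal Latent Gaussian Models of County-Level Insecticide Use
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: County-year panel analysis of relative insecticide use and
    landscape simplification. Implements preprocessing of Census of
    Agriculture style panels (censored-value imputation, minimum-cropland
    filtering, covariate centering), growing-degree-day computation from
    monthly temperature normals, a family of six Bayesian latent Gaussian
    models ranging from a plain Gaussian GLM to separable space-time models
    with intrinsic CAR (Besag) spatial structure evolving as an AR1 process
    (random intercepts and spatially varying coefficients), a blocked Gibbs
    sampler with sparse-precision linear algebra, DIC model comparison, PIT
    and residual-variogram diagnostics, and effect reporting. A synthetic
    county-lattice generator reproduces the statistical structure of the
    panel so the full pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
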