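test_that("grid lattices have the rook edge count and degree structure", {
  l22 <- make_grid_lattice(2, 2)
  expect_equal(l22$graph$n_nodes, 4)
  expect_equal(nrow(l22$graph$edges), 4)
  l15 <- make_grid_lattice(1, 5)
  expect_equal(nrow(l15$graph$edges), 4)
  expect_equal(l15$graph$n_components, 1)
  l33 <- make_grid_lattice(3, 3)
  deg <- tabulate(c(l33$graph$edges), nbins = 9)
  corner <- c(1, 3, 7, 9)
  expect_equal(deg[corner], rep(2, 4))
  expect_equal(deg[5], 4)
  expect_equal(nrow(l33$graph$edges), 3 * 2 + 3 * 2)
  expect_error(make_grid_lattice(0, 3), "positive")
})

test_that("simulation is deterministic given the seed", {
  a <- simulate_panel(sim_config(grid_rows = 4, grid_cols = 4, seed = 9))
  b <- simulate_panel(sim_config(grid_rows = 4, grid_cols = 4, seed = 9))
  expect_identical(a$panel$records, b$panel$records)
  expect_identical(a$panel$censored, b$panel$censored)
  c_ <- simulate_panel(sim_config(grid_rows = 4, grid_cols = 4, seed = 10))
  expect_false(identical(a$panel$records$y, c_$panel$records$y))
})

test_that("simulated proportion fields stay in range and shares sum below one", {
  sim <- cached_sim(rows = 8, cols = 8, seed = 2)
  rec <- sim$panel$records
  ok <- !is.na(rec$x_corn) & !is.na(rec$x_cov) & !is.na(rec$x_sw)
  for (f in c("x_corn", "x_cov", "x_sw", "x_crop")) {
    v <- rec[[f]][!is.na(rec[[f]])]
    expect_true(all(v >= 0 & v <= 1))
  }
  expect_true(all((rec$x_corn + rec$x_cov + rec$x_sw)[ok] <= 1 + 1e-6))
})

test_that("simulated covariate fields are spatially autocorrelated", {
  cfg <- sim_config(seed = 5, censor_prob = 0)
  lat <- make_grid_lattice(20, 20)
  panel <- simulate_covariates(lat, cfg)
  rec1 <- panel$records[panel$records$year == 1997, ]
  for (f in panel_covariates()) {
    expect_gt(morans_i(rec1[[f]], lat$graph), 0.2)
  }
})

test_that("the noiseless limit returns the fixed-effect surface exactly", {
  cfg <- sim_config(grid_rows = 4, grid_cols = 4, seed = 3, sigma = 0,
                    tau_space = Inf, tau_iid_county = Inf,
                    tau_iid_year = Inf, censor_prob = 0)
  lat <- make_grid_lattice(4, 4)
  panel <- simulate_covariates(lat, cfg)
  panel <- simulate_response(panel, lat$graph, cfg)
  centered <- center_covariates(panel)
  eta <- cfg$beta[["intercept"]] +
    as.matrix(centered$records[, panel_covariates()]) %*%
      cfg$beta[panel_covariates()] +
    cfg$beta[["year"]] * (centered$records$year - mean(cfg$years))
  expect_equal(panel$records$y, as.numeric(eta), tolerance = 1e-12)
})

test_that("random effects add variance beyond the residual noise", {
  # law of total variance: the variance of y around the fixed-effect
  # surface exceeds sigma^2 when the random-effect blocks are active
  excess <- vapply(1:8, function(s) {
    cfg <- sim_config(grid_rows = 6, grid_cols = 6, seed = 100 + s,
                      censor_prob = 0)
    sim <- simulate_panel(cfg, censor = FALSE)
    centered <- center_covariates(sim$panel)
    eta_fixed <- cfg$beta[["intercept"]] +
      as.matrix(centered$records[, panel_covariates()]) %*%
        cfg$beta[panel_covariates()] +
      cfg$beta[["year"]] * (centered$records$year - mean(cfg$years))
    var(sim$panel$records$y - as.numeric(eta_fixed)) - cfg$sigma^2
  }, numeric(1))
  expect_gt(mean(excess > 0), 0.8)
  expect_gt(mean(excess), 0)
})

test_that("rho = 0 gives year-independent space-time fields", {
  # Monte-Carlo lag-1 correlation of the field across years
  sim_lag1 <- function(rho, nrep = 60) {
    lat <- make_grid_lattice(5, 5)
    basis <- icar_basis(lat$graph)
    cors <- vapply(seq_len(nrep), function(r) {
      set.seed(5000 + r)
      u <- insectscape:::draw_spacetime_field(basis, 25, 4, rho, 1)
      mean(vapply(1:3, function(t) cor(u[, t], u[, t + 1]), numeric(1)))
    }, numeric(1))
    mean(cors)
  }
  expect_lt(abs(sim_lag1(0)), 0.06)
  expect_gt(sim_lag1(0.9), 0.7)
})

test_that("the simulated space-time field matches the Kronecker precision
           pseudo-inverse", {
  # 3x3 lattice x 3 years, empirical covariance over 2000 draws
  lat <- make_grid_lattice(3, 3)
  basis <- icar_basis(lat$graph)
  tau <- 2.5; rho <- 0.6
  set.seed(77)
  draws <- t(replicate(2000, as.numeric(
    insectscape:::draw_spacetime_field(basis, 9, 3, rho, tau))))
  emp <- cov(draws)
  S <- as.matrix(build_icar_structure(lat$graph))
  R <- solve(rho^abs(outer(1:3, 1:3, "-")))
  Qfull <- tau * kronecker(R, S)
  Sigma <- MASS::ginv(Qfull)
  expect_lt(max(abs(emp - Sigma)), 6 * max(diag(Sigma)) / sqrt(2000) * 3)
  # each year's field sums to zero (the constraint subspace)
  u <- insectscape:::draw_spacetime_field(basis, 9, 3, rho, tau)
  expect_equal(colSums(u), rep(0, 3), tolerance = 1e-10)
})

test_that("censoring masks at a binomial rate and round-trips through
           imputation", {
  cfg <- sim_config(grid_rows = 6, grid_cols = 6, seed = 8,
                    censor_prob = 0.1)
  sim <- simulate_panel(cfg, censor = TRUE)
  n_entries <- nrow(sim$panel$records) * length(panel_covariates())
  n_masked <- sum(sim$panel$censored)
  bounds <- qbinom(c(0.005, 0.995), n_entries, 0.1)
  expect_gte(n_masked, bounds[1])
  expect_lte(n_masked, bounds[2])
  imputed <- impute_censored(sim$panel)
  expect_false(any(imputed$censored))
  expect_false(anyNA(imputed$records[, panel_covariates()]))
  # censor_prob zero is the identity
  sim0 <- simulate_panel(sim_config(grid_rows = 4, grid_cols = 4, seed = 8,
                                    censor_prob = 0), censor = TRUE)
  expect_false(any(sim0$panel$censored))
})

test_that("simulated data files round-trip through the readers", {
  sim <- cached_sim(rows = 3, cols = 3, seed = 4)
  dir <- tempfile()
  write_simulated_data(sim, dir)
  panel <- read_panel(file.path(dir, "panel.csv"),
                      centroids = file.path(dir, "centroids.csv"))
  expect_equal(n_records(panel), n_records(sim$panel))
  expect_equal(panel$records$y, sim$panel$records$y)
  g <- build_adjacency(file.path(dir, "edges.csv"), panel)
  expect_equal(nrow(g$edges), nrow(sim$graph$edges))
})

test_that("simulation configs validate their parameters", {
  expect_error(sim_config(rho = 1.2), "rho")
  expect_error(sim_config(censor_prob = 1), "censor_prob")
  expect_error(sim_config(generative_model = 9), "generative_model")
  expect_error(sim_config(tau_space = -1), "positive")
})
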