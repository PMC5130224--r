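test_that("the ICAR structure matrix is degree-minus-adjacency", {
  panel <- toy_panel()
  g <- build_adjacency(data.frame(from = c("A", "B"), to = c("B", "C")),
                       panel)
  S <- as.matrix(build_icar_structure(g))
  expect_equal(S, matrix(c(1, -1, 0, -1, 2, -1, 0, -1, 1), 3, 3),
               ignore_attr = TRUE)
  expect_equal(rowSums(S), rep(0, 3), ignore_attr = TRUE)
})

test_that("ICAR rank is nodes minus components and kills constants", {
  sim <- cached_sim(rows = 2, cols = 2)
  S <- as.matrix(build_icar_structure(sim$graph))
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(ev > 1e-9), 3)  # 4 nodes, 1 component
  expect_equal(as.numeric(S %*% rep(1, 4)), rep(0, 4))
  # two components: path A-B plus isolated C
  g2 <- build_adjacency(data.frame(from = "A", to = "B"), toy_panel())
  S2 <- as.matrix(build_icar_structure(g2))
  ev2 <- eigen(S2, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(ev2 > 1e-9), 1)
})

test_that("AR1 precision matches its textbook form and inverts to the
           autocorrelation covariance", {
  expect_equal(as.matrix(build_ar1_precision(3, 0)), diag(3),
               ignore_attr = TRUE)
  got <- as.matrix(build_ar1_precision(2, 0.5))
  expect_equal(got, matrix(c(4 / 3, -2 / 3, -2 / 3, 4 / 3), 2, 2),
               ignore_attr = TRUE, tolerance = 1e-12)
  # dense inversion oracle for n up to 6
  for (n in 2:6) {
    for (rho in c(-0.7, 0.3, 0.9)) {
      Sigma <- rho^abs(outer(1:n, 1:n, "-"))
      expect_equal(as.matrix(build_ar1_precision(n, rho)), solve(Sigma),
                   ignore_attr = TRUE, tolerance = 1e-9)
    }
  }
  expect_error(build_ar1_precision(3, 1), "rho")
})

test_that("AR1 precision scales linearly with the marginal precision", {
  expect_equal(as.matrix(build_ar1_precision(4, 0.6, 2.5)),
               2.5 * as.matrix(build_ar1_precision(4, 0.6)),
               tolerance = 1e-12)
})

test_that("the space-time precision equals the hand-assembled Kronecker
           product on a 3-county path x 2 years", {
  panel <- toy_panel()
  g <- build_adjacency(data.frame(from = c("A", "B"), to = c("B", "C")),
                       panel)
  stp <- build_spacetime_precision(g, n_times = 2, rho = 0.4, tau = 3)
  S <- matrix(c(1, -1, 0, -1, 2, -1, 0, -1, 1), 3, 3)
  R <- solve(matrix(c(1, 0.4, 0.4, 1), 2, 2))
  expect_equal(as.matrix(stp$Q), 3 * kronecker(R, S),
               ignore_attr = TRUE, tolerance = 1e-9)
  expect_equal(stp$rank, 2 * (3 - 1))
  # constraints: one row per component per year
  expect_equal(dim(stp$A), c(2, 6))
  expect_equal(as.numeric(stp$A %*% rep(1, 6)), c(3, 3))
})

test_that("rho = 0 reduces the space-time precision to block-diagonal
           ICAR copies", {
  sim <- cached_sim(rows = 2, cols = 2)
  stp <- build_spacetime_precision(sim$graph, n_times = 3, rho = 0,
                                   tau = 2)
  S <- as.matrix(build_icar_structure(sim$graph))
  expect_equal(as.matrix(stp$Q), kronecker(diag(3), 2 * S),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("space-time null space has one dimension per component-year and
           the constraints remove all of it", {
  panel <- toy_panel()
  g <- build_adjacency(data.frame(from = "A", to = "B"), panel)  # 2 comps
  stp <- build_spacetime_precision(g, n_times = 2, rho = 0.5, tau = 1)
  Qd <- as.matrix(stp$Q)
  ev <- eigen(Qd, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(ev) < 1e-9), 2 * 2)  # components x years
  # projecting onto the constraint null space leaves a positive definite form
  N <- MASS::Null(t(as.matrix(stp$A)))
  evc <- eigen(t(N) %*% Qd %*% N, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(evc > 1e-10))
})

test_that("space-time precision is homogeneous of degree one in tau and
           exactly symmetric", {
  sim <- cached_sim(rows = 3, cols = 3)
  a <- build_spacetime_precision(sim$graph, 4, 0.7, 1)$Q
  b <- build_spacetime_precision(sim$graph, 4, 0.7, 5.5)$Q
  expect_equal(as.matrix(b), 5.5 * as.matrix(a), tolerance = 1e-12)
  expect_true(Matrix::isSymmetric(a))
})

test_that("model specs carry the prescribed latent blocks", {
  sim <- cached_sim(rows = 3, cols = 3)
  pp <- preprocess_panel(sim$panel)
  g <- restrict_graph(sim$graph, pp)
  expect_length(make_model_spec(1, pp)$blocks, 0)
  kinds4 <- vapply(make_model_spec(4, pp)$blocks, `[[`, "", "kind")
  expect_setequal(kinds4, c("iid_county", "iid_year"))
  spec5 <- make_model_spec(5, pp, g)
  kinds5 <- vapply(spec5$blocks, `[[`, "", "kind")
  expect_setequal(kinds5, c("iid_county", "iid_year", "icar_ar1_slope"))
  slope <- spec5$blocks[[which(kinds5 == "icar_ar1_slope")]]
  expect_equal(slope$covariate, "x_crop")
  kinds6 <- vapply(make_model_spec(6, pp, g)$blocks, `[[`, "", "kind")
  expect_setequal(kinds6, c("iid_county", "iid_year", "icar_ar1_intercept"))
  expect_error(make_model_spec(7, pp), "1..6")
  expect_error(make_model_spec(5, pp), "graph")
})

test_that("design matrices have the documented shape and priors", {
  sim <- cached_sim(rows = 6, cols = 6)  # four synthetic states
  pp <- preprocess_panel(sim$panel)
  dm1 <- build_design_matrix(make_model_spec(1, pp), pp)
  expect_equal(ncol(dm1$X), 8)   # intercept + 7 covariates
  expect_equal(dm1$prior_prec, c(0, rep(0.001, 7)))
  n_states <- length(unique(pp$records$state_id))
  dm2 <- build_design_matrix(make_model_spec(2, pp), pp)
  expect_equal(ncol(dm2$X), 8 + (n_states - 1) + 1)
  # year covariate is centered calendar years
  expect_equal(sort(unique(dm2$X[, "year"])), c(-7.5, -2.5, 2.5, 7.5))
  dm4 <- build_design_matrix(make_model_spec(4, pp), pp)
  expect_equal(ncol(dm4$X), 9)
  dm3 <- build_design_matrix(make_model_spec(3, pp), pp)
  expect_equal(ncol(dm3$X), 8 + (n_states - 1) + 1 +
                 (n_states - 1) + 1 + (n_states - 1))
  # interactions are elementwise products of their parents
  s <- sort(unique(pp$records$state_id))[2]
  expect_equal(dm3$X[, paste0("state_", s, ":x_crop")],
               dm3$X[, paste0("state_", s)] * pp$records$x_crop,
               ignore_attr = TRUE)
})

test_that("an all-zero covariate column triggers a warning", {
  sim <- cached_sim(rows = 3, cols = 3)
  pp <- preprocess_panel(sim$panel)
  pp$records$x_sw <- 0
  expect_warning(build_design_matrix(make_model_spec(1, pp), pp),
                 "all-zero")
})
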