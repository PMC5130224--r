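# Synthetic county-lattice panels.
#
# Generates panels with the statistical structure the analysis assumes: a
# rook-adjacency lattice standing in for the county map, spatially smooth
# covariate fields in realistic ranges, and a response drawn from the
# latent Gaussian model with the chosen random-effect blocks active.
# Default parameter values are the fitted space-time model's posterior
# means, so recovery experiments target the printed values.

#' Simulation configuration
#'
#' @param grid_rows,grid_cols Lattice dimensions.
#' @param years Census years (default 1997, 2002, 2007, 2012).
#' @param seed Integer RNG seed; all generator output is deterministic
#'   given the seed (R's default Mersenne-Twister RNG).
#' @param beta Named fixed-effect values: intercept, the seven covariates,
#'   and year. Defaults are the fitted space-time model's posterior means.
#' @param sigma Residual standard deviation (default 0.054).
#' @param tau_space Precision scale of the CAR-within-AR1 block (default
#'   1/0.150^2).
#' @param rho AR1 correlation of the space-time block (default 0.708).
#' @param tau_iid_county,tau_iid_year Precisions of the exchangeable
#'   county and year intercepts (defaults 1/0.005^2 and 1/0.008^2).
#' @param censor_prob Probability a covariate entry is masked (default
#'   0.05, emulating census anonymity suppression).
#' @param generative_model Which model's random-effect blocks generate the
#'   response (1-6): 1-3 none, 4 adds exchangeable county and year
#'   intercepts, 5 adds a CAR-within-AR1 slope on proportion cropland, 6
#'   adds a CAR-within-AR1 intercept.
#' @param state_block Side length of the square blocks of lattice cells
#'   that share a synthetic state id (default 5).
#' @return A `sim_config` list.
#' @export
sim_config <- function(grid_rows = 20, grid_cols = 20,
                       years = c(1997L, 2002L, 2007L, 2012L),
                       seed = 1L,
                       beta = c(intercept = 0.265, x_corn = 0.398,
                                x_cov = 0.605, x_sw = 0.041,
                                x_income = 0.004, x_size = 0.012,
                                x_gdd = 0.030, x_crop = 0.050,
                                year = 0.005),
                       sigma = 0.054,
                       tau_space = 1 / 0.150^2,
                       rho = 0.708,
                       tau_iid_county = 1 / 0.005^2,
                       tau_iid_year = 1 / 0.008^2,
                       censor_prob = 0.05,
                       generative_model = 6L,
                       state_block = 5L) {
  stopifnot(grid_rows >= 1, grid_cols >= 1, length(years) >= 1)
  if (abs(rho) >= 1) stop("rho must lie in (-1, 1)", call. = FALSE)
  if (any(c(tau_space, tau_iid_county, tau_iid_year) <= 0) || sigma < 0) {
    stop("precisions must be positive", call. = FALSE)
  }
  if (censor_prob < 0 || censor_prob >= 1) {
    stop("censor_prob must lie in [0, 1)", call. = FALSE)
  }
  if (!generative_model %in% 1:6) {
    stop("generative_model must be one of 1..6", call. = FALSE)
  }
  need <- c("intercept", panel_covariates(), "year")
  if (!all(need %in% names(beta))) {
    stop("beta must name: ", paste(need, collapse = ", "), call. = FALSE)
  }
  structure(list(grid_rows = grid_rows, grid_cols = grid_cols,
                 years = sort(as.integer(years)), seed = as.integer(seed),
                 beta = beta[need], sigma = sigma, tau_space = tau_space,
                 rho = rho, tau_iid_county = tau_iid_county,
                 tau_iid_year = tau_iid_year, censor_prob = censor_prob,
                 generative_model = as.integer(generative_model),
                 state_block = as.integer(state_block)),
            class = "sim_config")
}

#' Rook-adjacency grid lattice with centroids
#'
#' Builds the synthetic stand-in for the county map: a rows x cols grid
#' whose cells are counties, adjacent when they share an edge, with
#' centroids at unit (1 km) spacing. States are square blocks of cells.
#'
#' @param rows,cols Lattice dimensions (>= 1).
#' @param state_block Side length of the state blocks (default 5).
#' @return List with `graph` (an `adjacency_graph`), `centroids` (data
#'   frame county_id, x_km, y_km), `states` (named character vector
#'   county_id -> state_id), and `edge_ids` (two-column data frame of
#'   county-id pairs, the on-disk edge-list format).
#' @export
make_grid_lattice <- function(rows, cols, state_block = 5L) {
  if (rows < 1 || cols < 1) {
    stop("lattice dimensions must be positive", call. = FALSE)
  }
  n <- rows * cols
  ids <- sprintf("c%04d", seq_len(n))
  cell <- function(r, c) (c - 1) * rows + r
  rr <- rep(seq_len(rows), cols)
  cc <- rep(seq_len(cols), each = rows)
  i1 <- integer(0); i2 <- integer(0)
  right <- which(cc < cols)
  down <- which(rr < rows)
  i1 <- c(down, right)
  i2 <- c(down + 1L, right + rows)
  edges <- cbind(i = pmin(i1, i2), j = pmax(i1, i2))
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::add_edges(g, as.vector(t(edges)))
  comp <- igraph::components(g)
  graph <- structure(
    list(n_nodes = n, node_ids = ids, edges = edges,
         components = comp$membership, n_components = comp$no,
         isolated = ids[igraph::degree(g) == 0]),
    class = "adjacency_graph")
  centroids <- data.frame(county_id = ids, x_km = as.numeric(cc),
                          y_km = as.numeric(rr), stringsAsFactors = FALSE)
  sb <- max(1L, state_block)
  states <- sprintf("s%02d", (ceiling(rr / sb) - 1) *
                      ceiling(cols / sb) + ceiling(cc / sb))
  list(graph = graph, centroids = centroids,
       states = stats::setNames(states, ids),
       edge_ids = data.frame(from = ids[edges[, 1]], to = ids[edges[, 2]],
                             stringsAsFactors = FALSE))
}

#' Spectral basis of the intrinsic CAR structure
#'
#' Eigen-decomposition of the Besag structure matrix restricted to its
#' row space (the sum-to-zero subspace of each connected component), used
#' to draw intrinsic CAR fields exactly on small-to-moderate lattices.
#'
#' @param graph An `adjacency_graph`.
#' @return List with `V` (n x r eigenvector matrix) and `lambda` (the r
#'   positive eigenvalues).
#' @export
icar_basis <- function(graph) {
  S <- build_icar_structure(graph)
  ev <- eigen(as.matrix(S), symmetric = TRUE)
  pos <- ev$values > max(ev$values) * 1e-9
  list(V = ev$vectors[, pos, drop = FALSE], lambda = ev$values[pos])
}

# One intrinsic CAR draw per column of z; returns n x ncol(z).
icar_draw <- function(basis, z) {
  basis$V %*% (z / sqrt(basis$lambda))
}

# Smooth standardized lattice field: intrinsic CAR draw plus small iid
# jitter, standardized to mean 0, sd 1.
smooth_field <- function(basis, n) {
  f <- as.numeric(icar_draw(basis, matrix(stats::rnorm(length(basis$lambda)),
                                          ncol = 1)))
  f <- f + stats::rnorm(n, sd = 0.1 * stats::sd(f))
  as.numeric(scale(f))
}

#' Simulate spatially structured covariates on a lattice
#'
#' Each covariate is a spatially smooth Gaussian field (intrinsic CAR with
#' small independent jitter), carried through a transform appropriate to
#' its scale: a shared multinomial-logistic transform for the three crop
#' shares (so their sum stays below 1), a logistic transform for
#' proportion cropland, affine/log-linear maps into realistic ranges for
#' income (thousand USD/ha, may be negative), farm size (km^2 per
#' operator) and growing degree days (thousands). Fields persist across
#' years with small year-specific perturbations. Deterministic given the
#' seed.
#'
#' @param lattice Output of [make_grid_lattice()].
#' @param config A [sim_config()].
#' @param basis Optional precomputed [icar_basis()] of the lattice graph.
#' @return An un-centered `coa_panel` with covariates filled and `y` set
#'   to `NA`.
#' @export
simulate_covariates <- function(lattice, config, basis = NULL) {
  set.seed(config$seed)
  graph <- lattice$graph
  n <- graph$n_nodes
  if (is.null(basis)) basis <- icar_basis(graph)
  T_ <- length(config$years)
  w <- 0.3  # share of year-specific variation in each field

  field_panel <- function() {
    base <- smooth_field(basis, n)
    vapply(seq_len(T_), function(t) {
      sqrt(1 - w^2) * base + w * stats::rnorm(n)
    }, numeric(n))
  }
  f_corn <- field_panel(); f_cov <- field_panel(); f_sw <- field_panel()
  f_income <- field_panel(); f_size <- field_panel()
  f_gdd <- field_panel(); f_crop <- field_panel()

  # crop shares through a shared multinomial logistic so corn+cov+sw < 1
  e_corn <- exp(-1.2 + 0.8 * f_corn)
  e_cov <- exp(-2.2 + 0.8 * f_cov)
  e_sw <- exp(-1.0 + 0.8 * f_sw)
  denom <- 1 + e_corn + e_cov + e_sw
  x_corn <- e_corn / denom
  x_cov <- e_cov / denom
  x_sw <- e_sw / denom
  x_income <- 0.61 + 0.45 * f_income
  x_size <- 1.196 * exp(0.5 * f_size - 0.125)
  x_gdd <- pmin(pmax(3.0 + 1.1 * f_gdd, 0.4), 6.2)
  x_crop <- stats::plogis(-0.95 + 1.2 * f_crop)

  ids <- graph$node_ids
  records <- data.frame(
    county_id = rep(ids, T_),
    state_id = rep(unname(lattice$states[ids]), T_),
    year = rep(config$years, each = n),
    y = NA_real_,
    x_corn = as.numeric(x_corn), x_cov = as.numeric(x_cov),
    x_sw = as.numeric(x_sw), x_income = as.numeric(x_income),
    x_size = as.numeric(x_size), x_gdd = as.numeric(x_gdd),
    x_crop = as.numeric(x_crop),
    stringsAsFactors = FALSE)
  coa_panel(records, centroids = lattice$centroids, years = config$years)
}

# Draw the CAR-within-AR1 field: n x T matrix whose vec (county-fastest)
# has covariance (1/tau) * Sigma_ar1 kron pinv(S_icar); each year's field
# sums to zero within every graph component.
draw_spacetime_field <- function(basis, n, T_, rho, tau) {
  Sigma <- rho^abs(outer(seq_len(T_), seq_len(T_), "-"))
  L <- t(chol(Sigma))
  M <- icar_draw(basis, matrix(stats::rnorm(length(basis$lambda) * T_),
                               ncol = T_))
  (M %*% t(L)) / sqrt(tau)
}

#' Simulate the response from the latent Gaussian model
#'
#' Centers a copy of the covariates, forms the linear predictor from
#' `config$beta` (intercept, the seven covariates, and centered continuous
#' year), adds the random-effect draws selected by
#' `config$generative_model`, and draws Gaussian observation noise. The
#' realized latent effects are kept in `panel$truth` for recovery testing.
#'
#' @param panel Panel with covariates (un-centered is fine; a centered
#'   copy is used internally and the returned panel keeps the input
#'   scale).
#' @param graph The lattice `adjacency_graph`.
#' @param config A [sim_config()].
#' @param basis Optional precomputed [icar_basis()].
#' @return The panel with `y` filled and `truth` attached: list with
#'   `beta`, `eta`, `b_county`, `c_year`, `u` (n x years matrix of the
#'   space-time field, when active).
#' @export
simulate_response <- function(panel, graph, config, basis = NULL) {
  set.seed(config$seed + 1L)
  gm <- config$generative_model
  centered <- if (isTRUE(panel$centered)) panel else {
    p <- panel; p$censored[] <- FALSE; center_covariates(p)
  }
  rec <- centered$records
  nobs <- nrow(rec)
  covs <- panel_covariates()
  eta <- config$beta[["intercept"]] +
    as.matrix(rec[, covs]) %*% config$beta[covs] +
    config$beta[["year"]] * year_covariate(rec$year, config$years)
  eta <- as.numeric(eta)

  n <- graph$n_nodes
  T_ <- length(config$years)
  ci <- panel$county_index[rec$county_id]
  ti <- match(rec$year, config$years)
  truth <- list(beta = config$beta, b_county = NULL, c_year = NULL,
                u = NULL)
  if (gm >= 4) {
    truth$b_county <- stats::rnorm(n, sd = 1 / sqrt(config$tau_iid_county))
    truth$c_year <- stats::rnorm(T_, sd = 1 / sqrt(config$tau_iid_year))
    eta <- eta + truth$b_county[ci] + truth$c_year[ti]
  }
  if (gm %in% 5:6) {
    if (T_ < 2) stop("space-time blocks require at least 2 years",
                     call. = FALSE)
    if (is.null(basis)) basis <- icar_basis(graph)
    truth$u <- draw_spacetime_field(basis, n, T_, config$rho,
                                    config$tau_space)
    eta <- eta + if (gm == 5) {
      truth$u[cbind(ci, ti)] * rec$x_crop
    } else {
      truth$u[cbind(ci, ti)]
    }
  }
  truth$eta <- eta
  panel$records$y <- eta + stats::rnorm(nobs, sd = config$sigma)
  panel$truth <- truth
  panel
}

#' Mask covariate entries at random
#'
#' Each covariate entry is independently masked (set to `NA` and flagged
#' censored) with probability `config$censor_prob`, emulating census
#' anonymity suppression. Deterministic given the seed.
#'
#' @param panel A `coa_panel`.
#' @param config A [sim_config()].
#' @return The panel with masked entries flagged for [impute_censored()].
#' @export
simulate_censoring <- function(panel, config) {
  if (config$censor_prob == 0) return(panel)
  set.seed(config$seed + 2L)
  for (f in panel_covariates()) {
    hit <- stats::runif(nrow(panel$records)) < config$censor_prob
    panel$records[[f]][hit] <- NA_real_
    panel$censored[hit, f] <- TRUE
  }
  panel
}

#' Generate a complete synthetic panel
#'
#' Lattice, covariates, response, and censoring in one call.
#'
#' @param config A [sim_config()].
#' @param censor Apply covariate censoring (default `TRUE`).
#' @return List with `panel` (un-centered, censored), `graph`, `lattice`,
#'   and `basis` (reusable across replicates on the same lattice).
#' @export
simulate_panel <- function(config = sim_config(), censor = TRUE) {
  lattice <- make_grid_lattice(config$grid_rows, config$grid_cols,
                               config$state_block)
  basis <- icar_basis(lattice$graph)
  panel <- simulate_covariates(lattice, config, basis)
  panel <- simulate_response(panel, lattice$graph, config, basis)
  if (censor) panel <- simulate_censoring(panel, config)
  list(panel = panel, graph = lattice$graph, lattice = lattice,
       basis = basis)
}

#' Write a simulated panel to the on-disk formats the reader accepts
#'
#' Emits `panel.csv`, `edges.csv` and `centroids.csv` under `dir` in the
#' formats [read_panel()] and [build_adjacency()] read.
#'
#' @param sim Output of [simulate_panel()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulated_data <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_panel(sim$panel, file.path(dir, "panel.csv"))
  utils::write.csv(sim$lattice$edge_ids, file.path(dir, "edges.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(sim$lattice$centroids, file.path(dir, "centroids.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
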