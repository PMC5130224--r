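# Declarative specification of the six latent Gaussian models and the
# sparse precision structures behind their random effects.
#
# All six models share a Gaussian likelihood with identity link:
#   y_it ~ N(eta_it, sigma^2),
#   eta_it = beta0 + sum_m beta_m x_mit + sum_l f_l(z_lit).
# Models differ in the fixed-effect set and in which latent blocks f_l are
# present. The space-time blocks use a separable precision: Kronecker
# product of a stationary AR1 precision over years and an intrinsic CAR
# (Besag) structure over counties.

#' Intrinsic CAR (Besag) structure matrix of a graph
#'
#' Returns the unscaled structure matrix D - W (degree minus adjacency).
#' Row sums are zero; the rank is n minus the number of connected
#' components. No generalized-variance rescaling is applied (a scaled
#' variant can be obtained with `scale = TRUE`, which rescales so the
#' geometric mean of the marginal variances on the constrained subspace
#' is one).
#'
#' @param graph An `adjacency_graph`.
#' @param scale Logical; apply generalized-variance rescaling (default
#'   `FALSE`).
#' @return A sparse symmetric `Matrix` of dimension n x n.
#' @export
build_icar_structure <- function(graph, scale = FALSE) {
  n <- graph$n_nodes
  if (is.null(n) || n < 1) stop("empty graph", call. = FALSE)
  e <- graph$edges
  if (nrow(e) > 0) {
    W <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                              x = 1, dims = c(n, n))
    S <- Matrix::Diagonal(x = Matrix::rowSums(W)) - W
  } else {
    S <- Matrix::Diagonal(n, x = 0)
  }
  S <- Matrix::forceSymmetric(S, "U")
  if (scale) {
    ev <- eigen(as.matrix(S), symmetric = TRUE)
    pos <- ev$values > max(ev$values) * 1e-9
    # marginal variances of the constrained intrinsic field
    mv <- rowSums(sweep(ev$vectors[, pos, drop = FALSE]^2, 2,
                        ev$values[pos], "/"))
    S <- S * exp(mean(log(mv)))
  }
  S
}

#' Precision matrix of a stationary AR1 process
#'
#' Tridiagonal precision of an AR1 with unit marginal variance, scaled by
#' `marginal_precision`: interior diagonal (1+rho^2)/(1-rho^2), ends
#' 1/(1-rho^2), off-diagonal -rho/(1-rho^2).
#'
#' @param n_times Number of time points (>= 1).
#' @param rho AR1 correlation, |rho| < 1.
#' @param marginal_precision Marginal precision scale (default 1).
#' @return A sparse symmetric `Matrix` of dimension n_times x n_times.
#' @export
build_ar1_precision <- function(n_times, rho, marginal_precision = 1) {
  if (abs(rho) >= 1) stop("|rho| must be below 1", call. = FALSE)
  if (n_times < 1) stop("n_times must be at least 1", call. = FALSE)
  if (n_times == 1) {
    return(Matrix::Matrix(marginal_precision, 1, 1, sparse = TRUE))
  }
  s <- 1 / (1 - rho^2)
  d <- c(s, rep((1 + rho^2) * s, n_times - 2), s)
  R <- Matrix::bandSparse(n_times, k = c(0, 1),
                          diagonals = list(d, rep(-rho * s, n_times - 1)),
                          symmetric = TRUE)
  Matrix::forceSymmetric(R * marginal_precision, "U")
}

#' Separable space-time precision (AR1 over years, ICAR over counties)
#'
#' Kronecker product of the AR1 precision over years (unit marginal
#' variance) and the intrinsic CAR structure over counties, scaled by
#' `tau`. Effect indices run county-fastest: element (t-1)*n + i is county
#' i in year t. Also returns the identifying linear constraints: the
#' effects sum to zero over the counties of each connected component,
#' within each year.
#'
#' @param graph An `adjacency_graph`.
#' @param n_times Number of years.
#' @param rho AR1 correlation.
#' @param tau Overall precision scale (> 0).
#' @return A list with `Q` (sparse precision, (n*n_times)^2), `A` (sparse
#'   constraint matrix, one row per component per year), `rank` (rank of
#'   Q), and the parts `S_icar`, `R_ar1`.
#' @export
build_spacetime_precision <- function(graph, n_times, rho, tau = 1) {
  if (tau <= 0) stop("tau must be positive", call. = FALSE)
  if (n_times < 2) stop("space-time blocks require at least 2 years",
                        call. = FALSE)
  S <- build_icar_structure(graph)
  R <- build_ar1_precision(n_times, rho)
  Q <- Matrix::forceSymmetric(tau * Matrix::kronecker(R, S), "U")
  n <- graph$n_nodes
  comp <- graph$components
  rows <- integer(0); cols <- integer(0)
  for (t in seq_len(n_times)) {
    for (k in seq_len(graph$n_components)) {
      members <- which(comp == k)
      rows <- c(rows, rep((t - 1) * graph$n_components + k, length(members)))
      cols <- c(cols, (t - 1) * n + members)
    }
  }
  A <- Matrix::sparseMatrix(i = rows, j = cols, x = 1,
                            dims = c(n_times * graph$n_components,
                                     n * n_times))
  list(Q = Q, A = A, rank = n_times * (n - graph$n_components),
       S_icar = S, R_ar1 = R)
}

latent_block_kinds <- function() {
  c("iid_county", "iid_year", "icar_ar1_intercept", "icar_ar1_slope")
}

latent_block <- function(kind, covariate = NULL) {
  kind <- match.arg(kind, latent_block_kinds())
  if (kind == "icar_ar1_slope" && is.null(covariate)) {
    stop("slope blocks must name a covariate", call. = FALSE)
  }
  list(kind = kind, covariate = covariate,
       # Gamma(shape, rate) on the block precision; the classical
       # log-gamma prior on the log precision.
       prec_prior = c(shape = 1, rate = 0.00005),
       # Normal(mean 0, precision 0.15) on log((1+rho)/(1-rho))
       rho_prior = if (grepl("^icar_ar1", kind)) {
         c(mean = 0, precision = 0.15)
       } else NULL)
}

#' Specify one of the six insecticide-use models
#'
#' Model 1: intercept + the 7 covariates (plain Gaussian GLM). Model 2:
#' adds a state factor (reference coding, first sorted state as reference)
#' and continuous year. Model 3: adds state x cropland, year x cropland
#' and state x year x cropland interactions. Model 4: Model 1 terms + year
#' + exchangeable county and year random intercepts. Model 5: Model 4 + a
#' CAR-within-AR1 spatially varying slope on proportion cropland. Model 6:
#' Model 4 + a CAR-within-AR1 structured random intercept.
#'
#' Priors: flat intercept (precision 0), Normal(0, precision 0.001) on all
#' other fixed effects, Gamma(1, 0.00005) on every precision (error and
#' block), Normal(0, precision 0.15) on the transformed AR1 correlation.
#'
#' @param model_id Integer 1-6.
#' @param panel The (preprocessed) `coa_panel` the model will be fitted
#'   to; supplies state levels.
#' @param graph `adjacency_graph`; required for models 5 and 6.
#' @return An object of class `lgm_spec`.
#' @export
make_model_spec <- function(model_id, panel, graph = NULL) {
  if (!model_id %in% 1:6) {
    stop("model_id must be one of 1..6", call. = FALSE)
  }
  if (model_id %in% 5:6 && is.null(graph)) {
    stop("models 5 and 6 require an adjacency graph", call. = FALSE)
  }
  blocks <- list()
  if (model_id >= 4) {
    blocks <- list(latent_block("iid_county"), latent_block("iid_year"))
  }
  if (model_id == 5) {
    blocks <- c(blocks, list(latent_block("icar_ar1_slope", "x_crop")))
  }
  if (model_id == 6) {
    blocks <- c(blocks, list(latent_block("icar_ar1_intercept")))
  }
  structure(
    list(model_id = model_id,
         states = sort(unique(panel$records$state_id)),
         years = panel$years,
         blocks = blocks,
         error_prec_prior = c(shape = 1, rate = 0.00005)),
    class = "lgm_spec")
}

#' @export
print.lgm_spec <- function(x, ...) {
  kinds <- vapply(x$blocks, `[[`, "", "kind")
  cat(sprintf("lgm_spec: Model %d, latent blocks: %s\n", x$model_id,
              if (length(kinds) > 0) paste(kinds, collapse = ", ")
              else "none"))
  invisible(x)
}

# Centered continuous year covariate in calendar-year units
# (1997/2002/2007/2012 -> -7.5/-2.5/+2.5/+7.5).
year_covariate <- function(years_obs, years) {
  as.numeric(years_obs) - mean(as.numeric(years))
}

#' Build the fixed-effect design matrix of a model
#'
#' Deterministic column order: intercept, the 7 covariates in canonical
#' order, then (models 2-3) state dummies in sorted-id order with the
#' first state as reference and centered continuous year, then (model 3)
#' the interaction columns. Interaction columns are elementwise products
#' of their parents.
#'
#' @param spec An `lgm_spec`.
#' @param panel A centered `coa_panel`.
#' @return List with `X` (n x p numeric matrix), `names`, `prior_mean`,
#'   `prior_prec` (per-column prior precisions; 0 for the intercept).
#' @export
build_design_matrix <- function(spec, panel) {
  rec <- panel$records
  covs <- panel_covariates()
  absent <- setdiff(covs, names(rec))
  if (length(absent) > 0) {
    stop("panel lacks covariate(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  X <- cbind(intercept = rep(1, nrow(rec)),
             as.matrix(rec[, covs, drop = FALSE]))
  if (spec$model_id %in% 2:3) {
    states <- spec$states
    for (s in states[-1]) {
      X <- cbind(X, as.numeric(rec$state_id == s))
      colnames(X)[ncol(X)] <- paste0("state_", s)
    }
    X <- cbind(X, year = year_covariate(rec$year, spec$years))
  }
  if (spec$model_id %in% 4:6) {
    X <- cbind(X, year = year_covariate(rec$year, spec$years))
  }
  if (spec$model_id == 3) {
    yearc <- year_covariate(rec$year, spec$years)
    states <- spec$states
    state_counts <- table(rec$state_id)
    small <- names(state_counts)[state_counts < 3]
    if (length(small) > 0) {
      warning("state(s) with fewer than 3 records give near-singular ",
              "interaction columns: ", paste(small, collapse = ", "),
              call. = FALSE)
    }
    for (s in states[-1]) {
      X <- cbind(X, as.numeric(rec$state_id == s) * rec$x_crop)
      colnames(X)[ncol(X)] <- paste0("state_", s, ":x_crop")
    }
    X <- cbind(X, "year:x_crop" = yearc * rec$x_crop)
    for (s in states[-1]) {
      X <- cbind(X, as.numeric(rec$state_id == s) * yearc * rec$x_crop)
      colnames(X)[ncol(X)] <- paste0("state_", s, ":year:x_crop")
    }
  }
  zero_cols <- colnames(X)[apply(X, 2, function(v) all(v == 0))]
  if (length(zero_cols) > 0) {
    warning("all-zero design column(s): ",
            paste(zero_cols, collapse = ", "), call. = FALSE)
  }
  prior_prec <- c(0, rep(0.001, ncol(X) - 1))
  list(X = X, names = colnames(X),
       prior_mean = rep(0, ncol(X)), prior_prec = prior_prec)
}
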