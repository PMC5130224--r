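# Blocked Gibbs sampler for the latent Gaussian models.
#
# The joint update draws all Gaussian quantities (fixed effects and every
# latent block) at once from their Gaussian full conditional using a
# sparse Cholesky factorization of the joint precision, with sum-to-zero
# constraints on intrinsic blocks enforced by conditioning-by-kriging.
# Precisions (error and block) have conjugate Gamma full conditionals;
# each AR1 correlation is updated by random-walk Metropolis on
# log((1+rho)/(1-rho)), with proposal scale adapted toward 0.44
# acceptance during burn-in only.
#
# The joint precision has a fixed sparsity pattern across iterations, so
# it is assembled by scattering precomputed component values into a
# pattern template and refactorized with a reused symbolic analysis
# (supernodal CHOLMOD update).

#' Sampler configuration
#'
#' @param n_iterations Total MCMC iterations (default 10000).
#' @param n_burnin Burn-in iterations discarded (default 2000).
#' @param thin Thinning interval for stored draws (default 5).
#' @param seed Integer RNG seed; identical seed and config give a
#'   bit-identical draw sequence.
#' @param proposal_sd Initial random-walk scale for each transformed AR1
#'   correlation (default 0.3).
#' @param adapt_window Iterations per adaptation step during burn-in
#'   (default 50).
#' @param fix_sigma2 Optional fixed error variance. With it set (and no
#'   latent blocks) the posterior of the fixed effects is exactly
#'   Gaussian, which the conjugate oracle tests exploit.
#' @param keep_latent Store thinned draws of every latent block (default
#'   `TRUE`; running means are always kept).
#' @param keep_mu Store thinned draws of the linear predictor, needed for
#'   posterior-predictive replication (default `FALSE`).
#' @return A `sampler_config` list.
#' @export
sampler_config <- function(n_iterations = 10000, n_burnin = 2000, thin = 5,
                           seed = 1L, proposal_sd = 0.3, adapt_window = 50,
                           fix_sigma2 = NULL, keep_latent = TRUE,
                           keep_mu = FALSE) {
  if (!(n_iterations > n_burnin) || n_burnin < 0 || thin < 1) {
    stop("need n_iterations > n_burnin >= 0 and thin >= 1", call. = FALSE)
  }
  structure(list(n_iterations = as.integer(n_iterations),
                 n_burnin = as.integer(n_burnin), thin = as.integer(thin),
                 seed = as.integer(seed), proposal_sd = proposal_sd,
                 adapt_window = as.integer(adapt_window),
                 fix_sigma2 = fix_sigma2, keep_latent = keep_latent,
                 keep_mu = keep_mu),
            class = "sampler_config")
}

# Observation matrix of one latent block (sparse n_obs x block dim).
block_design <- function(block, panel, graph) {
  rec <- panel$records
  nobs <- nrow(rec)
  ci <- panel$county_index[rec$county_id]
  ti <- match(rec$year, panel$years)
  n <- length(panel$county_index)
  T_ <- length(panel$years)
  switch(block$kind,
    iid_county = Matrix::sparseMatrix(i = seq_len(nobs), j = ci, x = 1,
                                      dims = c(nobs, n)),
    iid_year = Matrix::sparseMatrix(i = seq_len(nobs), j = ti, x = 1,
                                    dims = c(nobs, T_)),
    icar_ar1_intercept = Matrix::sparseMatrix(
      i = seq_len(nobs), j = (ti - 1L) * n + ci, x = 1,
      dims = c(nobs, n * T_)),
    icar_ar1_slope = Matrix::sparseMatrix(
      i = seq_len(nobs), j = (ti - 1L) * n + ci,
      x = rec[[block$covariate]], dims = c(nobs, n * T_)))
}

# Upper-triangle triplets (i <= j) of a symmetric sparse matrix,
# optionally shifted by `off` along the diagonal of a larger matrix.
ut_triplets <- function(M, off = 0L) {
  Mc <- as(Matrix::forceSymmetric(M, "U"), "CsparseMatrix")
  list(i = Mc@i + 1L + off,
       j = rep.int(seq_len(ncol(Mc)), diff(Mc@p)) + off,
       x = Mc@x)
}

# One N(0, Q^{-1}) draw given the (possibly permuted, LDL' or LL')
# CHOLMOD factor of Q. For the unit-diagonal LDL' representation the
# standard normal vector must be scaled by D^{-1/2} before the
# triangular solve.
gmrf_noise <- function(ch, z, ldl) {
  if (ldl) z <- z / sqrt(Matrix::diag(ch))
  as.numeric(Matrix::solve(ch, Matrix::solve(ch, z, system = "Lt"),
                           system = "Pt"))
}

rho_to_z <- function(rho) log((1 + rho) / (1 - rho))
z_to_rho <- function(z) tanh(z / 2)

# AR1 precision entries (unit marginal variance) split by position:
# ends a = 1/(1-rho^2), interior b = (1+rho^2)/(1-rho^2),
# off-diagonal c = -rho/(1-rho^2).
ar1_coefs <- function(rho) {
  s <- 1 / (1 - rho^2)
  c(ends = s, mid = (1 + rho^2) * s, off = -rho * s)
}

# log p(u | tau, rho) terms that depend on rho for a CAR-within-AR1
# block, using the precomputed T x T cross matrix M = U' S U.
rho_logdens <- function(rho, M, tau, n_minus_c, T_) {
  R <- as.matrix(build_ar1_precision(T_, rho))
  -0.5 * n_minus_c * (T_ - 1) * log(1 - rho^2) - 0.5 * tau * sum(R * M)
}

#' Fit a latent Gaussian model by blocked Gibbs sampling
#'
#' @param spec An `lgm_spec` from [make_model_spec()].
#' @param panel A centered `coa_panel`.
#' @param graph `adjacency_graph` over exactly the panel's counties;
#'   required when the spec has space-time blocks.
#' @param config A [sampler_config()].
#' @return An object of class `lgm_fit`: thinned post-burn-in draws of the
#'   fixed effects, error variance, block precisions (stored as standard
#'   deviations) and AR1 correlations; running posterior means of the
#'   linear predictor and each latent block; per-observation PIT values
#'   and residuals (posterior-predictive mean minus observed); the
#'   deviance trace, DIC and pD; Metropolis acceptance rates; and the
#'   seed/spec provenance.
#' @export
fit_model <- function(spec, panel, graph = NULL,
                      config = sampler_config()) {
  if (!isTRUE(panel$centered)) {
    stop("panel must be centered before fitting (see center_covariates)",
         call. = FALSE)
  }
  needs_graph <- any(vapply(spec$blocks, function(b)
    grepl("^icar_ar1", b$kind), logical(1)))
  if (needs_graph && is.null(graph)) {
    stop("this model's space-time blocks require an adjacency graph",
         call. = FALSE)
  }
  if (needs_graph && graph$n_nodes != length(panel$county_index)) {
    stop("graph has ", graph$n_nodes, " nodes but the panel has ",
         length(panel$county_index), " counties; restrict the graph ",
         "to the filtered panel (see restrict_graph)", call. = FALSE)
  }
  set.seed(config$seed)
  y <- panel$records$y
  nobs <- length(y)
  dm <- build_design_matrix(spec, panel)
  p <- ncol(dm$X)
  T_ <- length(panel$years)
  n_cty <- length(panel$county_index)

  parts <- list(Matrix::Matrix(dm$X, sparse = TRUE))
  block_dims <- integer(0)
  for (b in spec$blocks) {
    Z <- block_design(b, panel, graph)
    parts <- c(parts, list(Z))
    block_dims <- c(block_dims, ncol(Z))
  }
  W <- do.call(cbind, parts)
  dim_all <- ncol(W)
  offs <- p + c(0L, cumsum(block_dims))  # block l occupies offs[l]+1..offs[l+1]
  WtW <- Matrix::forceSymmetric(Matrix::crossprod(W), "U")
  Wty <- as.numeric(Matrix::crossprod(W, y))

  nb <- length(spec$blocks)
  kinds <- if (nb > 0) vapply(spec$blocks, `[[`, "", "kind") else character(0)
  is_st <- grepl("^icar_ar1", kinds)

  # --- precision components with fixed pattern -------------------------
  # Each component is a triplet list; per iteration its values enter the
  # template with a scalar coefficient.
  comp <- list(
    prior_fixed = ut_triplets(Matrix::Diagonal(p, x = dm$prior_prec)),
    wtw = ut_triplets(WtW))
  st_mats <- vector("list", nb)
  A <- NULL
  if (any(is_st)) {
    S_icar <- build_icar_structure(graph)
    st_rank <- T_ * (n_cty - graph$n_components)
    stp <- build_spacetime_precision(graph, T_, rho = 0.5, tau = 1)
    # Regularizer inside the constraint rowspace: outer products of the
    # year-1 component-sum rows. On the constrained subspace it
    # contributes nothing, so the constrained draw is exact, but it
    # removes the joint null direction that pairs the flat-prior
    # intercept (or a global slope) with a constant intrinsic field,
    # making the joint precision positive definite.
    Mreg <- Matrix::forceSymmetric(Matrix::crossprod(
      stp$A[seq_len(graph$n_components), , drop = FALSE]), "U")
    E_ends <- Matrix::sparseMatrix(i = c(1L, T_), j = c(1L, T_), x = 1,
                                   dims = c(T_, T_))
    E_mid <- Matrix::Diagonal(T_) - E_ends
    E_off <- Matrix::bandSparse(T_, k = 1, diagonals = list(rep(1, T_ - 1)),
                                symmetric = TRUE)
    Ablocks <- list()
  }
  for (l in seq_len(nb)) {
    if (is_st[l]) {
      st_mats[[l]] <- list(
        ends = ut_triplets(Matrix::kronecker(E_ends, S_icar), offs[l]),
        mid = ut_triplets(Matrix::kronecker(E_mid, S_icar), offs[l]),
        off = ut_triplets(Matrix::kronecker(E_off, S_icar), offs[l]),
        reg = ut_triplets(Mreg, offs[l]))
      Asub <- stp$A
      Ablocks[[length(Ablocks) + 1]] <- cbind(
        Matrix::Matrix(0, nrow(Asub), offs[l], sparse = TRUE), Asub,
        Matrix::Matrix(0, nrow(Asub), dim_all - offs[l + 1], sparse = TRUE))
    } else {
      st_mats[[l]] <- list(
        diag = ut_triplets(Matrix::Diagonal(block_dims[l]), offs[l]))
    }
  }
  if (any(is_st)) A <- do.call(rbind, Ablocks)
  tA_dense <- if (!is.null(A)) as.matrix(Matrix::t(A)) else NULL

  # template with the union pattern; slot index map per component
  all_i <- unlist(lapply(c(comp, unlist(st_mats, recursive = FALSE)),
                         `[[`, "i"))
  all_j <- unlist(lapply(c(comp, unlist(st_mats, recursive = FALSE)),
                         `[[`, "j"))
  QT <- Matrix::sparseMatrix(i = all_i, j = all_j, x = 1,
                             dims = c(dim_all, dim_all), symmetric = TRUE,
                             use.last.ij = TRUE)
  slot_key <- QT@i + 1 + as.numeric(dim_all) *
    (rep.int(seq_len(dim_all), diff(QT@p)) - 1)
  slot_of <- function(tr) {
    idx <- match(tr$i + as.numeric(dim_all) * (tr$j - 1), slot_key)
    if (anyNA(idx)) stop("internal: pattern mismatch", call. = FALSE)
    idx
  }
  comp_idx <- lapply(comp, slot_of)
  st_idx <- lapply(st_mats, function(ms) lapply(ms, slot_of))
  nnzQ <- length(slot_key)

  # --- sampler state ---------------------------------------------------
  sigma2 <- if (is.null(config$fix_sigma2)) stats::var(y) / 2 else
    config$fix_sigma2
  taus <- rep(100, nb)
  rhos <- rep(0.5, nb)
  prop_sd <- rep(config$proposal_sd, nb)
  acc_count <- rep(0L, nb); try_count <- rep(0L, nb)
  win_acc <- rep(0L, nb); win_try <- rep(0L, nb)
  e_shape <- spec$error_prec_prior[["shape"]]
  e_rate <- spec$error_prec_prior[["rate"]]

  n_keep <- (config$n_iterations - config$n_burnin) %/% config$thin
  beta_draws <- matrix(NA_real_, n_keep, p, dimnames = list(NULL, dm$names))
  sigma2_draws <- numeric(n_keep)
  tau_draws <- if (nb > 0) matrix(NA_real_, n_keep, nb,
                                  dimnames = list(NULL, kinds)) else NULL
  rho_draws <- if (any(is_st)) matrix(NA_real_, n_keep, sum(is_st),
                                      dimnames = list(NULL, kinds[is_st]))
    else NULL
  latent_draws <- if (config$keep_latent && nb > 0) {
    lapply(seq_len(nb), function(l) matrix(NA_real_, n_keep, block_dims[l]))
  } else NULL
  mu_draws <- if (config$keep_mu) matrix(NA_real_, n_keep, nobs) else NULL
  dev_trace <- numeric(n_keep)
  mu_accum <- numeric(nobs)
  pit_accum <- numeric(nobs)
  latent_accum <- lapply(seq_len(nb), function(l) numeric(block_dims[l]))

  ch <- NULL
  ldl <- FALSE
  keep_i <- 0L
  for (iter in seq_len(config$n_iterations)) {
    # --- assemble joint precision into the template --------------------
    xs <- numeric(nnzQ)
    xs[comp_idx$prior_fixed] <- comp$prior_fixed$x
    xs[comp_idx$wtw] <- xs[comp_idx$wtw] + comp$wtw$x / sigma2
    for (l in seq_len(nb)) {
      if (is_st[l]) {
        co <- ar1_coefs(rhos[l])
        ms <- st_mats[[l]]; mi <- st_idx[[l]]
        xs[mi$ends] <- xs[mi$ends] + taus[l] * co[["ends"]] * ms$ends$x
        if (length(mi$mid) > 0) {
          xs[mi$mid] <- xs[mi$mid] + taus[l] * co[["mid"]] * ms$mid$x
        }
        xs[mi$off] <- xs[mi$off] + taus[l] * co[["off"]] * ms$off$x
        xs[mi$reg] <- xs[mi$reg] + taus[l] * ms$reg$x
      } else {
        mi <- st_idx[[l]]$diag
        xs[mi] <- xs[mi] + taus[l] * st_mats[[l]]$diag$x
      }
    }
    QT@x <- xs
    if (is.null(ch)) {
      ch <- Matrix::Cholesky(QT, LDLt = FALSE, perm = TRUE, super = TRUE)
      ldl <- tryCatch(Matrix::isLDL(ch), error = function(e) FALSE)
    } else {
      ch <- Matrix::update(ch, QT)
    }

    # --- joint Gaussian draw of (beta, all latent blocks) --------------
    b <- Wty / sigma2
    if (is.null(tA_dense)) {
      mu_c <- as.numeric(Matrix::solve(ch, b, system = "A"))
      xs_draw <- mu_c + gmrf_noise(ch, stats::rnorm(dim_all), ldl)
    } else {
      sol <- as.matrix(Matrix::solve(ch, cbind(b, tA_dense), system = "A"))
      mu_c <- sol[, 1]
      V <- sol[, -1, drop = FALSE]
      xs_draw <- mu_c + gmrf_noise(ch, stats::rnorm(dim_all), ldl)
      Wk <- crossprod(tA_dense, V)
      xs_draw <- xs_draw - as.numeric(
        V %*% solve(Wk, crossprod(tA_dense, xs_draw)))
    }
    theta <- xs_draw
    mu_lin <- as.numeric(W %*% theta)
    if (!all(is.finite(mu_lin))) {
      stop("non-finite linear predictor at iteration ", iter, call. = FALSE)
    }

    # --- conjugate error precision -------------------------------------
    if (is.null(config$fix_sigma2)) {
      ssr <- sum((y - mu_lin)^2)
      sigma2 <- 1 / stats::rgamma(1, shape = e_shape + nobs / 2,
                                  rate = e_rate + ssr / 2)
    }

    # --- block precisions and AR1 correlations -------------------------
    for (l in seq_len(nb)) {
      u <- theta[(offs[l] + 1):offs[l + 1]]
      pr <- spec$blocks[[l]]$prec_prior
      if (is_st[l]) {
        U <- matrix(u, n_cty, T_)
        M <- as.matrix(Matrix::crossprod(U, S_icar %*% U))
        R <- as.matrix(build_ar1_precision(T_, rhos[l]))
        q <- sum(R * M)
        taus[l] <- stats::rgamma(1, shape = pr[["shape"]] + st_rank / 2,
                                 rate = pr[["rate"]] + q / 2)
        z0 <- rho_to_z(rhos[l])
        z1 <- z0 + stats::rnorm(1, sd = prop_sd[l])
        rp <- spec$blocks[[l]]$rho_prior
        lp0 <- rho_logdens(rhos[l], M, taus[l],
                           n_cty - graph$n_components, T_) -
          0.5 * rp[["precision"]] * (z0 - rp[["mean"]])^2
        lp1 <- rho_logdens(z_to_rho(z1), M, taus[l],
                           n_cty - graph$n_components, T_) -
          0.5 * rp[["precision"]] * (z1 - rp[["mean"]])^2
        try_count[l] <- try_count[l] + 1L
        win_try[l] <- win_try[l] + 1L
        if (log(stats::runif(1)) < lp1 - lp0) {
          rhos[l] <- z_to_rho(z1)
          acc_count[l] <- acc_count[l] + 1L
          win_acc[l] <- win_acc[l] + 1L
        }
      } else {
        taus[l] <- stats::rgamma(1, shape = pr[["shape"]] +
                                   block_dims[l] / 2,
                                 rate = pr[["rate"]] + sum(u^2) / 2)
      }
    }
    if (iter <= config$n_burnin && iter %% config$adapt_window == 0) {
      for (l in which(is_st)) {
        if (win_try[l] > 0) {
          prop_sd[l] <- prop_sd[l] * exp(win_acc[l] / win_try[l] - 0.44)
        }
      }
      win_acc[] <- 0L; win_try[] <- 0L
    }

    # --- storage --------------------------------------------------------
    if (iter > config$n_burnin &&
        (iter - config$n_burnin) %% config$thin == 0) {
      keep_i <- keep_i + 1L
      beta_draws[keep_i, ] <- theta[seq_len(p)]
      sigma2_draws[keep_i] <- sigma2
      if (nb > 0) tau_draws[keep_i, ] <- taus
      if (any(is_st)) rho_draws[keep_i, ] <- rhos[is_st]
      dev_trace[keep_i] <- -2 * sum(stats::dnorm(y, mu_lin, sqrt(sigma2),
                                                 log = TRUE))
      mu_accum <- mu_accum + mu_lin
      pit_accum <- pit_accum + stats::pnorm((y - mu_lin) / sqrt(sigma2))
      if (!is.null(mu_draws)) mu_draws[keep_i, ] <- mu_lin
      for (l in seq_len(nb)) {
        u <- theta[(offs[l] + 1):offs[l + 1]]
        latent_accum[[l]] <- latent_accum[[l]] + u
        if (!is.null(latent_draws)) latent_draws[[l]][keep_i, ] <- u
      }
    }
  }

  mu_mean <- mu_accum / n_keep
  sigma2_mean <- mean(sigma2_draws)
  dev_at_mean <- -2 * sum(stats::dnorm(y, mu_mean, sqrt(sigma2_mean),
                                       log = TRUE))
  dic <- compute_dic(dev_trace, dev_at_mean)

  structure(
    list(model_id = spec$model_id,
         spec = spec,
         terms = dm$names,
         draws = list(beta = beta_draws, sigma2 = sigma2_draws,
                      tau = tau_draws, rho = rho_draws,
                      latent = latent_draws, mu = mu_draws),
         latent_mean = stats::setNames(
           lapply(latent_accum, function(v) v / n_keep), kinds),
         mu_mean = mu_mean,
         pit = pit_accum / n_keep,
         residuals = mu_mean - y,
         deviance_trace = dev_trace,
         deviance_at_mean = dev_at_mean,
         dic = dic$dic, pd = dic$pd,
         acceptance = ifelse(try_count > 0, acc_count / try_count, NA),
         n_kept = n_keep,
         n_obs = nobs,
         block_dims = block_dims,
         kinds = kinds,
         config = config,
         spec_hash = sum(utf8ToInt(paste(spec$model_id,
                                         paste(kinds, collapse = ","))))),
    class = "lgm_fit")
}

#' @export
print.lgm_fit <- function(x, ...) {
  cat(sprintf(
    "lgm_fit: Model %d, %d observations, %d kept draws, DIC %.1f (pD %.1f)\n",
    x$model_id, x$n_obs, x$n_kept, x$dic, x$pd))
  invisible(x)
}

#' Deviance Information Criterion from a deviance trace
#'
#' pD is the mean posterior deviance minus the deviance at the posterior
#' mean; DIC is the mean deviance plus pD. pD can be negative in
#' pathological fits and is reported as-is.
#'
#' @param deviance_trace Numeric vector of per-draw deviances.
#' @param deviance_at_posterior_mean Deviance evaluated at the posterior
#'   means of the predictor and error variance.
#' @return List with `dic` and `pd`.
#' @export
compute_dic <- function(deviance_trace, deviance_at_posterior_mean) {
  if (length(deviance_trace) == 0) {
    stop("empty deviance trace", call. = FALSE)
  }
  dbar <- mean(deviance_trace)
  pd <- dbar - deviance_at_posterior_mean
  list(dic = dbar + pd, pd = pd)
}

#' DIC differences from the best model
#'
#' @param dics Named numeric vector (or list) of DIC values by model.
#' @return Named numeric of DIC differences; the best model has 0.
#' @export
delta_dic <- function(dics) {
  dics <- unlist(dics)
  if (length(dics) == 0) stop("no DIC values supplied", call. = FALSE)
  dics - min(dics)
}

#' Probability integral transform values of a fit
#'
#' PIT_i is the posterior-predictive probability that a replicate
#' observation falls at or below the observed value: the average over
#' draws of Phi((y_i - mu_i)/sigma). Values are accumulated over the kept
#' draws during sampling. Note this is the conditional (in-sample)
#' posterior-predictive transform, not the leave-one-out variant; for
#' flexible models it concentrates toward 0.5 on the fitted data, which
#' is why calibration checks use [replicate_pit()].
#'
#' @param fit An `lgm_fit`.
#' @param panel The panel the model was fitted to (consistency check
#'   only).
#' @return Numeric vector in [0, 1], one value per observation.
#' @export
compute_pit <- function(fit, panel = NULL) {
  if (!is.null(panel) && nrow(panel$records) != fit$n_obs) {
    stop("panel does not match the fitted observation count", call. = FALSE)
  }
  fit$pit
}

#' PIT of replicate data drawn from the posterior predictive
#'
#' Draws a replicate data vector from the fitted model's posterior
#' predictive distribution (one posterior draw of the predictor and error
#' variance, then Gaussian noise) and computes its PIT against the full
#' set of kept draws. Replicates drawn from the predictive mixture have
#' exactly uniform PIT, so this is the calibration check for the PIT
#' machinery and for model adequacy.
#'
#' @param fit An `lgm_fit` run with `keep_mu = TRUE`.
#' @param n_rep Number of replicate vectors (default 1).
#' @return Matrix of PIT values, one column per replicate.
#' @export
replicate_pit <- function(fit, n_rep = 1) {
  if (is.null(fit$draws$mu)) {
    stop("fit was run without keep_mu = TRUE", call. = FALSE)
  }
  mu <- fit$draws$mu
  sig <- sqrt(fit$draws$sigma2)
  out <- matrix(NA_real_, fit$n_obs, n_rep)
  for (r in seq_len(n_rep)) {
    s <- sample.int(fit$n_kept, 1)
    y_rep <- stats::rnorm(fit$n_obs, mu[s, ], sig[s])
    acc <- numeric(fit$n_obs)
    for (k in seq_len(fit$n_kept)) {
      acc <- acc + stats::pnorm((y_rep - mu[k, ]) / sig[k])
    }
    out[, r] <- acc / fit$n_kept
  }
  out
}

#' Posterior summary table
#'
#' Empirical posterior means, central interval quantiles, and the tail
#' probability P(parameter <= 0) for every fixed effect, standard
#' deviation component (error and block SDs), and AR1 correlation.
#'
#' @param fit An `lgm_fit`.
#' @param level Central credible level (default 0.95); e.g. 0.80 gives an
#'   80 percent interval.
#' @return Data frame with columns term, mean, lower, upper, p_le_0.
#' @export
posterior_summary <- function(fit, level = 0.95) {
  a <- (1 - level) / 2
  summarise <- function(x) c(mean(x), stats::quantile(x, c(a, 1 - a)),
                             mean(x <= 0))
  rows <- list()
  for (j in seq_len(ncol(fit$draws$beta))) {
    rows[[length(rows) + 1]] <- c(term = colnames(fit$draws$beta)[j],
                                  summarise(fit$draws$beta[, j]))
  }
  rows[[length(rows) + 1]] <- c(term = "sd_error",
                                summarise(sqrt(fit$draws$sigma2)))
  if (!is.null(fit$draws$tau)) {
    for (j in seq_len(ncol(fit$draws$tau))) {
      rows[[length(rows) + 1]] <- c(
        term = paste0("sd_", colnames(fit$draws$tau)[j]),
        summarise(1 / sqrt(fit$draws$tau[, j])))
    }
  }
  if (!is.null(fit$draws$rho)) {
    for (j in seq_len(ncol(fit$draws$rho))) {
      rows[[length(rows) + 1]] <- c(
        term = paste0("rho_", colnames(fit$draws$rho)[j]),
        summarise(fit$draws$rho[, j]))
    }
  }
  out <- do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE))
  names(out) <- c("term", "mean", "lower", "upper", "p_le_0")
  for (k in 2:5) out[[k]] <- as.numeric(out[[k]])
  rownames(out) <- NULL
  out
}
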