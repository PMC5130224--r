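# Residual diagnostics: empirical variograms with Matern fits and PIT
# histogram summaries, used to adjudicate competing models. A model that
# captures the spatial structure leaves residuals with a flat variogram
# (partial sill near zero relative to the nugget); uncaptured structure
# shows as semivariance rising with distance.

#' Posterior-predictive residuals
#'
#' Residuals are the means of the posterior predictive distributions minus
#' the observed values: residual_i = E[mu_i | y] - y_i.
#'
#' @param fit An `lgm_fit`.
#' @param panel The panel the model was fitted to.
#' @return Numeric vector, one residual per observation.
#' @export
compute_residuals <- function(fit, panel = NULL) {
  if (!is.null(panel) && nrow(panel$records) != fit$n_obs) {
    stop("panel does not match the fitted observation count", call. = FALSE)
  }
  fit$residuals
}

#' Residual table for mapping
#'
#' @param fit An `lgm_fit`.
#' @param panel The fitted panel.
#' @return Data frame county_id, year, residual, suitable for any mapping
#'   tool.
#' @export
residual_table <- function(fit, panel) {
  data.frame(county_id = panel$records$county_id,
             year = panel$records$year,
             residual = compute_residuals(fit, panel),
             stringsAsFactors = FALSE)
}

#' Empirical semivariogram
#'
#' Binned method-of-moments semivariances: for each distance bin,
#' gamma(bin) = sum over pairs in the bin of (r_i - r_j)^2 / (2 N_bin).
#' Distances are Euclidean on the planar centroid coordinates
#' (kilometres). Bins are equal-width up to `max_dist`, by default half
#' the maximum pairwise distance. Values are computed one year at a time
#' (pass a single year's residuals and coordinates).
#'
#' @param values Numeric vector of residuals (one spatial unit each).
#' @param coords Two-column matrix or data frame of planar coordinates in
#'   km, same row count as `values`.
#' @param n_bins Number of distance bins (default 15).
#' @param max_dist Maximum pairwise distance considered; default half the
#'   maximum observed distance.
#' @return Object of class `variogram_estimate`: data frame `bins` with
#'   columns center, semivariance, n_pairs; plus `max_dist`.
#' @export
empirical_variogram <- function(values, coords, n_bins = 15,
                                max_dist = NULL) {
  coords <- as.matrix(coords)
  if (length(values) < 2) {
    stop("variogram needs at least 2 points", call. = FALSE)
  }
  stopifnot(nrow(coords) == length(values), ncol(coords) == 2)
  d <- as.numeric(stats::dist(coords))
  if (is.null(max_dist)) max_dist <- max(d) / 2
  pairs <- which(d <= max_dist & d > 0)
  dv <- as.numeric(stats::dist(values))^2
  breaks <- seq(0, max_dist, length.out = n_bins + 1)
  bin <- cut(d[pairs], breaks, include.lowest = TRUE, labels = FALSE)
  np <- tabulate(bin, nbins = n_bins)
  ssum <- vapply(seq_len(n_bins), function(k)
    sum(dv[pairs][bin == k]), numeric(1))
  gamma <- ifelse(np > 0, ssum / (2 * np), NA_real_)
  structure(
    list(bins = data.frame(center = (breaks[-1] + breaks[-(n_bins + 1)]) / 2,
                           semivariance = gamma, n_pairs = np),
         max_dist = max_dist),
    class = "variogram_estimate")
}

#' Residual variogram of a fitted model for one year
#'
#' @param fit An `lgm_fit`.
#' @param panel The fitted panel; must carry centroids.
#' @param year Census year to use.
#' @param ... Passed to [empirical_variogram()].
#' @return A `variogram_estimate`.
#' @export
residual_variogram <- function(fit, panel, year, ...) {
  if (is.null(panel$centroids)) {
    stop("panel has no centroids", call. = FALSE)
  }
  rows <- which(panel$records$year == year)
  r <- compute_residuals(fit, panel)[rows]
  xy <- panel$centroids[match(panel$records$county_id[rows],
                              panel$centroids$county_id),
                        c("x_km", "y_km")]
  empirical_variogram(r, xy, ...)
}

# Matern correlation, closed forms for half-integer smoothness.
matern_cor <- function(h, range, smoothness) {
  a <- h / range
  switch(as.character(smoothness),
         "0.5" = exp(-a),
         "1.5" = (1 + a) * exp(-a),
         "2.5" = (1 + a + a^2 / 3) * exp(-a),
         stop("smoothness must be one of 0.5, 1.5, 2.5", call. = FALSE))
}

#' Fit a Matern model to an empirical variogram
#'
#' Weighted least squares with Cressie-style weights (pair counts divided
#' by squared semivariance) over nugget, partial sill and range, with the
#' smoothness selected from {0.5, 1.5, 2.5} by best objective. The fitted
#' curve is gamma(h) = nugget + psill * (1 - rho_nu(h / range)).
#' Deterministic given the input. A degenerate (all-zero) variogram
#' returns a flagged nugget-only fit.
#'
#' @param vg A `variogram_estimate` with at least 4 non-empty bins.
#' @param smoothness Candidate smoothness values.
#' @return List with `nugget`, `psill`, `range`, `smoothness`,
#'   `objective` (WLS value), and `degenerate` flag.
#' @export
fit_matern_variogram <- function(vg, smoothness = c(0.5, 1.5, 2.5)) {
  b <- vg$bins[vg$bins$n_pairs > 0 & !is.na(vg$bins$semivariance), ]
  if (nrow(b) < 4) {
    stop("need at least 4 non-empty variogram bins", call. = FALSE)
  }
  if (all(b$semivariance == 0)) {
    return(list(nugget = 0, psill = 0, range = vg$max_dist / 3,
                smoothness = smoothness[1], objective = 0,
                degenerate = TRUE))
  }
  h <- b$center; g <- b$semivariance; np <- b$n_pairs
  wls <- function(par, nu) {
    nugget <- exp(par[1]); psill <- exp(par[2]); range <- exp(par[3])
    fitted <- nugget + psill * (1 - matern_cor(h, range, nu))
    w <- np / pmax(fitted, 1e-12)^2
    sum(w * (g - fitted)^2)
  }
  sill0 <- max(g); h0 <- max(h)
  # the range is confined to the sampled distance domain: below the
  # first bin centre a partial sill is indistinguishable from a nugget,
  # and above the last one the fitted sill describes structure the data
  # never express, making the psill/nugget split arbitrary either way
  lower <- c(log(sill0) - 18, log(sill0) - 18, log(min(h)))
  upper <- c(log(sill0) + 3, log(sill0) + 3, log(h0))
  starts <- list(c(log(sill0 / 2 + 1e-9), log(sill0 / 2 + 1e-9), log(h0 / 4)),
                 c(log(sill0 * 0.9 + 1e-9), log(sill0 * 0.1 + 1e-9),
                   log(h0 / 3)),
                 c(log(sill0 * 0.1 + 1e-9), log(sill0 * 0.9 + 1e-9),
                   log(max(h0 / 6, min(h)))))
  best <- NULL
  for (nu in smoothness) {
    for (s in starts) {
      opt <- stats::optim(pmin(pmax(s, lower), upper), wls, nu = nu,
                          method = "L-BFGS-B", lower = lower,
                          upper = upper,
                          control = list(maxit = 500, factr = 1e4))
      if (is.null(best) || opt$value < best$objective) {
        best <- list(nugget = exp(opt$par[1]), psill = exp(opt$par[2]),
                     range = exp(opt$par[3]), smoothness = nu,
                     objective = opt$value, degenerate = FALSE)
      }
    }
  }
  best
}

#' PIT histogram and uniformity statistic
#'
#' Equal-width histogram of PIT values on [0, 1] and the chi-square
#' statistic against the uniform expectation. A well-calibrated model
#' gives a histogram reasonably close to uniform.
#'
#' @param pit_values Numeric vector of PIT values in [0, 1].
#' @param n_bins Number of bins (default 20).
#' @return List with `counts`, `expected`, `chi_square`, `df`.
#' @export
pit_uniformity_summary <- function(pit_values, n_bins = 20) {
  if (length(pit_values) == 0) stop("empty PIT input", call. = FALSE)
  if (any(pit_values < 0 | pit_values > 1)) {
    stop("PIT values must lie in [0, 1]", call. = FALSE)
  }
  breaks <- seq(0, 1, length.out = n_bins + 1)
  counts <- tabulate(pmin(pmax(ceiling(pit_values * n_bins), 1L), n_bins),
                     nbins = n_bins)
  expected <- length(pit_values) / n_bins
  list(counts = counts, expected = expected,
       chi_square = sum((counts - expected)^2 / expected),
       df = n_bins - 1)
}
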