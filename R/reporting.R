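# Interpretive quantities from fitted models: effect translations on the
# response scale, standardized coefficients, spatially varying
# coefficients, and the side-by-side model comparison table.

# Round half away from zero (printed translations use this convention:
# 0.075 -> 0.08, not 0.07).
round_half_away <- function(x, digits) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Translate a slope into an implied change in relative insecticide use
#'
#' The implied change for a covariate moving from `from_value` to
#' `to_value` is coefficient x (to - from), rounded half-away-from-zero.
#'
#' @param coefficient Posterior-mean slope.
#' @param from_value,to_value Covariate values defining the contrast, in
#'   the covariate's native units.
#' @param decimals Rounding precision (default 2).
#' @return The implied change in relative insecticide use.
#' @export
effect_translation <- function(coefficient, from_value, to_value,
                               decimals = 2) {
  stopifnot(is.finite(coefficient), is.finite(from_value),
            is.finite(to_value))
  round_half_away(coefficient * (to_value - from_value), decimals)
}

#' Standardized coefficients of a fit
#'
#' Standardized slope = posterior-mean slope x standard deviation of the
#' covariate over all fitted records (not further divided by the response
#' SD; `scale_by_response_sd = TRUE` switches convention). Zero-variance
#' covariates are flagged and given standardized value 0.
#'
#' @param fit An `lgm_fit`.
#' @param panel The panel the model was fitted to.
#' @param scale_by_response_sd Also divide by sd(y) (default `FALSE`).
#' @return Data frame covariate, slope, sd_covariate, standardized,
#'   zero_variance.
#' @export
standardized_coefficients <- function(fit, panel,
                                      scale_by_response_sd = FALSE) {
  covs <- intersect(panel_covariates(), colnames(fit$draws$beta))
  slope <- colMeans(fit$draws$beta[, covs, drop = FALSE])
  sds <- vapply(covs, function(f) stats::sd(panel$records[[f]]), numeric(1))
  zero <- sds == 0
  if (any(zero)) {
    warning("zero-variance covariate(s): ",
            paste(covs[zero], collapse = ", "), call. = FALSE)
  }
  std <- ifelse(zero, 0, slope * sds)
  if (scale_by_response_sd) std <- std / stats::sd(panel$records$y)
  data.frame(covariate = covs, slope = as.numeric(slope),
             sd_covariate = as.numeric(sds),
             standardized = as.numeric(std),
             zero_variance = zero, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Spatially varying coefficients of the cropland effect
#'
#' For the model with a CAR-within-AR1 random slope on proportion
#' cropland, the per-county, per-year coefficient is the posterior mean of
#' the global cropland slope plus the county random slope.
#'
#' @param fit An `lgm_fit` containing an `icar_ar1_slope` block.
#' @param panel The fitted panel.
#' @return Data frame county_id, year, svc.
#' @export
svc_coefficients <- function(fit, panel) {
  l <- which(fit$kinds == "icar_ar1_slope")
  if (length(l) != 1) {
    stop("fit has no spatially varying slope block", call. = FALSE)
  }
  beta_crop <- mean(fit$draws$beta[, "x_crop"])
  u <- fit$latent_mean[["icar_ar1_slope"]]
  n <- length(panel$county_index)
  T_ <- length(panel$years)
  data.frame(county_id = rep(names(panel$county_index), T_),
             year = rep(panel$years, each = n),
             svc = beta_crop + u,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Side-by-side model comparison table
#'
#' One column per model: posterior mean (2.5, 97.5 percentiles) of each
#' fixed effect, the error and random-effect standard deviations, AR1
#' correlations, DIC and delta-DIC. Terms absent from a model are
#' rendered as a period.
#'
#' @param fits Named list of `lgm_fit` objects (names become column
#'   labels; unnamed lists are labelled by model id).
#' @return Data frame with a `term` column and one character column per
#'   model.
#' @export
comparison_table <- function(fits) {
  if (length(fits) == 0) stop("no fits supplied", call. = FALSE)
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- paste0("model_", vapply(fits, `[[`, 0, "model_id"))
  }
  summaries <- lapply(fits, posterior_summary)
  terms <- unique(unlist(lapply(summaries, `[[`, "term")))
  fmt <- function(s, term) {
    i <- match(term, s$term)
    if (is.na(i)) return(".")
    sprintf("%.3f (%.3f, %.3f)", s$mean[i], s$lower[i], s$upper[i])
  }
  out <- data.frame(term = terms, stringsAsFactors = FALSE)
  for (nm in names(fits)) {
    out[[nm]] <- vapply(terms, fmt, "", s = summaries[[nm]])
  }
  dics <- vapply(fits, `[[`, 0, "dic")
  dd <- delta_dic(dics)
  score_rows <- data.frame(term = c("DIC", "delta_DIC"),
                           stringsAsFactors = FALSE)
  for (k in seq_along(fits)) {
    score_rows[[names(fits)[k]]] <- sprintf("%.1f", c(dics[k], dd[k]))
  }
  out <- rbind(out, score_rows)
  rownames(out) <- NULL
  out
}
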