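# Growing degree days from monthly temperature normals.
#
# Thermal time accumulates as [(Tmax + Tmin)/2] - Tlower, with Tmin raised
# to the base temperature when below it and Tmax lowered to the upper
# threshold when above it; negative daily values are floored at zero when
# summing. Months are weighted by an average month length.

#' Growing-degree-day parameters
#'
#' @param t_lower Base temperature in degrees Celsius (default 8).
#' @param t_upper Upper threshold temperature in degrees Celsius
#'   (default 32).
#' @param days_per_month Average month length in days (default 30.4).
#' @return A `gdd_params` list.
#' @export
gdd_params <- function(t_lower = 8, t_upper = 32, days_per_month = 30.4) {
  if (!(t_lower < t_upper)) {
    stop("t_lower must be below t_upper", call. = FALSE)
  }
  structure(list(t_lower = t_lower, t_upper = t_upper,
                 days_per_month = days_per_month),
            class = "gdd_params")
}

#' Average daily growing degree days for a month
#'
#' Clamps the inputs to the (t_lower, t_upper) band before averaging:
#' `t_min` is raised to `t_lower` when below it, `t_max` lowered to
#' `t_upper` when above it. The result `(t_max' + t_min')/2 - t_lower` is
#' floored at zero. Vectorised over `t_min`/`t_max`.
#'
#' @param t_min Average daily minimum temperature for the month (degrees C).
#' @param t_max Average daily maximum temperature for the month (degrees C).
#' @param params A [gdd_params()] object.
#' @return Degree-days per day (non-negative).
#' @export
daily_gdd <- function(t_min, t_max, params = gdd_params()) {
  if (any(t_min > t_max)) {
    stop("t_min exceeds t_max", call. = FALSE)
  }
  lo <- pmax(t_min, params$t_lower)
  hi <- pmin(t_max, params$t_upper)
  pmax((hi + lo) / 2 - params$t_lower, 0)
}

#' Monthly growing degree days
#'
#' Average daily degree days multiplied by the average month length.
#'
#' @inheritParams daily_gdd
#' @return Degree-days per month.
#' @export
monthly_gdd <- function(t_min, t_max, params = gdd_params()) {
  daily_gdd(t_min, t_max, params) * params$days_per_month
}

#' Cumulative annual growing degree days
#'
#' Sum of monthly degree days over the twelve months of a year.
#'
#' @param t_min Numeric vector of 12 monthly average daily minima
#'   (degrees C).
#' @param t_max Numeric vector of 12 monthly average daily maxima.
#' @param params A [gdd_params()] object.
#' @return Degree-days per year (non-negative scalar).
#' @export
annual_gdd <- function(t_min, t_max, params = gdd_params()) {
  if (length(t_min) != 12 || length(t_max) != 12) {
    stop("annual_gdd() requires exactly 12 monthly values", call. = FALSE)
  }
  sum(monthly_gdd(t_min, t_max, params))
}

#' Merge annual GDD into a panel from monthly temperature records
#'
#' Reads (or accepts) a table of monthly temperatures per county and year,
#' computes cumulative annual degree days, and writes them into the
#' panel's `x_gdd` column in thousands of degree-days (the model's native
#' unit).
#'
#' @param panel A `coa_panel`.
#' @param temperatures Data frame (or path to a comma-delimited file) with
#'   columns county_id, year, month, t_min, t_max; twelve months per
#'   county-year.
#' @param params A [gdd_params()] object.
#' @return The panel with `x_gdd` filled for every county-year present in
#'   `temperatures`.
#' @export
add_gdd_to_panel <- function(panel, temperatures, params = gdd_params()) {
  if (is.character(temperatures)) {
    temperatures <- utils::read.csv(temperatures, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("county_id", "year", "month", "t_min", "t_max") %in%
                  names(temperatures)))
  key <- interaction(temperatures$county_id, temperatures$year, drop = TRUE)
  annual <- tapply(seq_len(nrow(temperatures)), key, function(rows) {
    rows <- rows[order(temperatures$month[rows])]
    annual_gdd(temperatures$t_min[rows], temperatures$t_max[rows], params)
  })
  rec_key <- paste(panel$records$county_id, panel$records$year, sep = ".")
  hit <- rec_key %in% names(annual)
  panel$records$x_gdd[hit] <- as.numeric(annual[rec_key[hit]]) / 1000
  panel
}
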