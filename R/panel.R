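# County-year panel container and preprocessing.
#
# The analysis panel holds one record per county and census year: the
# response y (relative insecticide use, a proportion of harvested cropland
# treated with insecticide) and seven covariates. Preprocessing follows the
# canonical order impute -> filter -> center.

#' Covariate column names of the analysis panel
#'
#' The seven fixed-effect covariates, in the canonical model order:
#' proportion of harvested cropland in corn grain and silage; proportion in
#' cotton, orchards and vegetables; proportion in soybean and wheat; net
#' farm income (thousand USD per harvested hectare); harvested cropland per
#' operator (square kilometres); annual growing degree days (thousands);
#' and proportion of county land in harvested cropland (landscape
#' simplification).
#'
#' @return Character vector of column names.
#' @export
panel_covariates <- function() {
  c("x_corn", "x_cov", "x_sw", "x_income", "x_size", "x_gdd", "x_crop")
}

panel_fields <- function() c("y", panel_covariates())

proportion_fields <- function() c("y", "x_corn", "x_cov", "x_sw", "x_crop")

#' Construct a county-year panel
#'
#' @param records Data frame with columns `county_id`, `state_id`, `year`,
#'   `y`, and the covariates of [panel_covariates()]. One row per
#'   county-year.
#' @param centroids Optional data frame with columns `county_id`, `x_km`,
#'   `y_km`: planar county-centroid coordinates in kilometres, used for
#'   residual variograms.
#' @param censored Optional logical matrix, same row count as `records`,
#'   with columns named after (a subset of) the panel fields; `TRUE` marks
#'   a withheld (censored) entry awaiting imputation.
#' @param years Census years the panel covers; defaults to the years
#'   present.
#' @param centered Logical; whether covariates have been centered.
#' @param covariate_means Named numeric of grand means recorded at
#'   centering time.
#'
#' @return An object of class `coa_panel`.
#' @export
coa_panel <- function(records, centroids = NULL, censored = NULL,
                      years = sort(unique(records$year)),
                      centered = FALSE, covariate_means = NULL) {
  required <- c("county_id", "state_id", "year", panel_fields())
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    stop("panel records are missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  records$county_id <- as.character(records$county_id)
  records$state_id <- as.character(records$state_id)
  records$year <- as.integer(records$year)
  if (anyDuplicated(paste(records$county_id, records$year))) {
    stop("duplicate (county_id, year) pair in panel records", call. = FALSE)
  }
  if (!all(records$year %in% years)) {
    stop("record year outside the configured census years", call. = FALSE)
  }
  if (is.null(censored)) {
    censored <- matrix(FALSE, nrow(records), length(panel_fields()),
                       dimnames = list(NULL, panel_fields()))
  }
  counties <- sort(unique(records$county_id))
  if (!is.null(centroids)) {
    centroids$county_id <- as.character(centroids$county_id)
    uncovered <- setdiff(counties, centroids$county_id)
    if (length(uncovered) > 0) {
      stop("counties without a centroid: ",
           paste(utils::head(uncovered, 5), collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(records = records,
         county_index = stats::setNames(seq_along(counties), counties),
         years = sort(as.integer(years)),
         centroids = centroids,
         censored = censored,
         centered = centered,
         covariate_means = covariate_means),
    class = "coa_panel")
}

#' @export
print.coa_panel <- function(x, ...) {
  cat(sprintf("coa_panel: %d records, %d counties, years %s%s\n",
              nrow(x$records), length(x$county_index),
              paste(x$years, collapse = "/"),
              if (x$centered) " (covariates centered)" else ""))
  invisible(x)
}

#' Number of records in a panel
#' @param panel A `coa_panel`.
#' @return Integer record count.
#' @export
n_records <- function(panel) nrow(panel$records)

#' Number of counties in a panel
#' @param panel A `coa_panel`.
#' @return Integer county count.
#' @export
n_counties <- function(panel) length(panel$county_index)

default_schema <- function() {
  nm <- c("county_id", "state_id", "year", panel_fields())
  stats::setNames(nm, nm)
}

#' Read a county-year panel from delimited text
#'
#' Reads a comma-delimited file with a header row, one county-year per
#' line. Missing (censored) values are encoded by an explicit sentinel;
#' they are flagged, not silently coerced.
#'
#' @param path Path to the delimited file.
#' @param schema Named character vector mapping canonical column names
#'   (names) to file column names (values); defaults to identity.
#' @param sentinel Token(s) marking a censored value; empty fields always
#'   count.
#' @param centroids Optional centroid data frame or path to a
#'   comma-delimited file with columns county_id, x_km, y_km.
#' @param years Census years; defaults to those present in the file.
#'
#' @return An un-centered [coa_panel()] with censored flags set wherever
#'   the sentinel occurred; row order preserved.
#' @export
read_panel <- function(path, schema = NULL, sentinel = "", centroids = NULL,
                       years = NULL) {
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = NULL)
  full_schema <- default_schema()
  if (!is.null(schema)) full_schema[names(schema)] <- schema
  missing_cols <- full_schema[!full_schema %in% names(raw)]
  if (length(missing_cols) > 0) {
    stop("panel file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  sentinels <- unique(c("", sentinel))
  fields <- panel_fields()
  records <- data.frame(county_id = raw[[full_schema["county_id"]]],
                        state_id = raw[[full_schema["state_id"]]],
                        stringsAsFactors = FALSE)
  yr_chr <- raw[[full_schema["year"]]]
  yr <- suppressWarnings(as.integer(yr_chr))
  if (anyNA(yr)) {
    stop("unparseable year at row(s): ",
         paste(utils::head(which(is.na(yr)), 5), collapse = ", "),
         call. = FALSE)
  }
  records$year <- yr
  censored <- matrix(FALSE, nrow(raw), length(fields),
                     dimnames = list(NULL, fields))
  for (f in fields) {
    chr <- raw[[full_schema[f]]]
    cens <- chr %in% sentinels | is.na(chr)
    val <- suppressWarnings(as.numeric(chr))
    bad <- which(!cens & is.na(val))
    if (length(bad) > 0) {
      stop(sprintf("unparseable numeric in column '%s' at row(s): %s",
                   full_schema[f], paste(utils::head(bad, 5), collapse = ", ")),
           call. = FALSE)
    }
    val[cens] <- NA_real_
    records[[f]] <- val
    censored[, f] <- cens
  }
  if (is.character(centroids)) {
    centroids <- utils::read.csv(centroids, stringsAsFactors = FALSE)
    names(centroids)[1:3] <- c("county_id", "x_km", "y_km")
  }
  if (is.null(years)) years <- sort(unique(records$year))
  coa_panel(records, centroids = centroids, censored = censored,
            years = years)
}

#' Write a panel to delimited text
#'
#' Inverse of [read_panel()]: censored entries are written as the sentinel.
#' Finite decimal values round-trip bit-for-bit (values are printed with
#' full precision).
#'
#' @param panel A `coa_panel`.
#' @param path Output file path.
#' @param sentinel Token used for censored entries.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, sentinel = "") {
  out <- panel$records
  for (f in colnames(panel$censored)) {
    col <- format(out[[f]], digits = 17, trim = TRUE, scientific = FALSE)
    col[panel$censored[, f]] <- sentinel
    out[[f]] <- col
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Impute censored panel entries
#'
#' Each censored field value is replaced by the mean of that county's
#' non-censored values of the same field across the census years; a county
#' censored in every year gets zero. Non-censored values are unchanged.
#'
#' @param panel An un-centered `coa_panel`.
#' @return The panel with all censored entries filled and an imputation
#'   report in `panel$imputation_report` (county, field, imputed value,
#'   zero-fallback flag).
#' @export
impute_censored <- function(panel) {
  if (isTRUE(panel$centered)) {
    stop("impute_censored() must run before centering", call. = FALSE)
  }
  rec <- panel$records
  report <- list()
  share_fields <- intersect(c("x_corn", "x_cov", "x_sw"),
                            colnames(panel$censored))
  share_imputed <- rowSums(panel$censored[, share_fields,
                                          drop = FALSE]) > 0
  for (f in colnames(panel$censored)) {
    flags <- panel$censored[, f]
    if (!any(flags)) next
    for (cid in unique(rec$county_id[flags])) {
      rows <- which(rec$county_id == cid)
      obs <- rec[[f]][rows][!flags[rows]]
      fill <- if (length(obs) > 0) mean(obs) else 0
      tgt <- rows[flags[rows]]
      rec[[f]][tgt] <- fill
      report[[length(report) + 1]] <- data.frame(
        county_id = cid, field = f, n_imputed = length(tgt),
        imputed_value = fill, zero_fallback = length(obs) == 0,
        stringsAsFactors = FALSE)
    }
    panel$censored[, f] <- FALSE
  }
  panel$records <- rec
  panel$imputation_report <- if (length(report) > 0) {
    do.call(rbind, report)
  } else {
    data.frame(county_id = character(), field = character(),
               n_imputed = integer(), imputed_value = numeric(),
               zero_fallback = logical())
  }
  validate_proportions(panel, share_imputed = share_imputed)
  panel
}

validate_proportions <- function(panel, share_imputed = NULL) {
  rec <- panel$records
  # y is excluded: the Gaussian observation model can put simulated or
  # fitted responses slightly outside [0, 1]
  for (f in setdiff(proportion_fields(), "y")) {
    v <- rec[[f]][!panel$censored[, f]]
    if (any(v < -1e-9 | v > 1 + 1e-9, na.rm = TRUE)) {
      stop("proportion field '", f, "' outside [0, 1]", call. = FALSE)
    }
  }
  share_sum <- rec$x_corn + rec$x_cov + rec$x_sw
  obs <- !(panel$censored[, "x_corn"] | panel$censored[, "x_cov"] |
             panel$censored[, "x_sw"])
  if (!is.null(share_imputed)) obs <- obs & !share_imputed
  if (any(share_sum[obs] > 1 + 1e-6, na.rm = TRUE)) {
    stop("crop shares x_corn + x_cov + x_sw exceed 1", call. = FALSE)
  }
  # county-mean imputation of individual shares can push a year's sum
  # past 1; the imputation rule is total, so this is reported, not fatal
  if (!is.null(share_imputed)) {
    over <- which(share_imputed & share_sum > 1 + 1e-6)
    if (length(over) > 0) {
      warning(length(over), " county-year(s) have imputed crop shares ",
              "summing above 1", call. = FALSE)
    }
  }
  invisible(panel)
}

#' Drop counties with too little harvested cropland
#'
#' Counties where harvested cropland is below `threshold` (as a proportion
#' of county land, strictly less-than) are removed. By default the rule is
#' applied at the county level: a county whose mean cropland proportion
#' across the census years falls below the threshold is dropped from all
#' years. `scope = "record"` instead drops individual county-years.
#'
#' @param panel An imputed `coa_panel`.
#' @param threshold Minimum proportion of county land in harvested crops
#'   (default 0.03).
#' @param scope `"county"` (default) or `"record"`.
#' @return The surviving panel, with a removal report in
#'   `panel$removal_report`.
#' @export
filter_min_cropland <- function(panel, threshold = 0.03,
                                scope = c("county", "record")) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold < 0 || threshold > 1) {
    stop("threshold must be a single proportion in [0, 1]", call. = FALSE)
  }
  scope <- match.arg(scope)
  rec <- panel$records
  if (scope == "county") {
    county_mean <- tapply(rec$x_crop, rec$county_id, mean)
    dropped_ids <- names(county_mean)[county_mean < threshold]
    keep <- !(rec$county_id %in% dropped_ids)
  } else {
    keep <- !(rec$x_crop < threshold)
    dropped_ids <- unique(rec$county_id[!keep])
  }
  removed <- rec[!keep, c("county_id", "year", "x_crop")]
  out <- coa_panel(rec[keep, , drop = FALSE],
                   centroids = if (is.null(panel$centroids)) NULL else
                     panel$centroids[panel$centroids$county_id %in%
                                       rec$county_id[keep], , drop = FALSE],
                   censored = panel$censored[keep, , drop = FALSE],
                   years = panel$years,
                   centered = panel$centered,
                   covariate_means = panel$covariate_means)
  out$imputation_report <- panel$imputation_report
  out$removal_report <- list(
    threshold = threshold, scope = scope,
    dropped_counties = sort(unique(as.character(dropped_ids))),
    n_records_removed = sum(!keep),
    removed = removed)
  out
}

#' Center panel covariates at their grand means
#'
#' Subtracts each covariate's mean over all surviving records and records
#' the means in `covariate_means`. The response y is never centered.
#' Centering an already-centered panel is a no-op up to numerical zero.
#'
#' @param panel An imputed, filtered `coa_panel`.
#' @return The centered panel.
#' @export
center_covariates <- function(panel) {
  if (n_records(panel) == 0) stop("cannot center an empty panel", call. = FALSE)
  means <- vapply(panel_covariates(),
                  function(f) mean(panel$records[[f]]), numeric(1))
  for (f in panel_covariates()) {
    panel$records[[f]] <- panel$records[[f]] - means[f]
  }
  if (is.null(panel$covariate_means)) {
    panel$covariate_means <- means
  } else {
    panel$covariate_means <- panel$covariate_means + means
  }
  panel$centered <- TRUE
  panel
}

#' Run the canonical preprocessing pipeline
#'
#' Equivalent to `center_covariates(filter_min_cropland(impute_censored(panel)))`.
#'
#' @param panel An un-centered `coa_panel`.
#' @param threshold Minimum-cropland threshold (default 0.03).
#' @param scope Filter scope; see [filter_min_cropland()].
#' @return The preprocessed panel.
#' @export
preprocess_panel <- function(panel, threshold = 0.03,
                             scope = c("county", "record")) {
  center_covariates(
    filter_min_cropland(impute_censored(panel), threshold,
                        match.arg(scope)))
}

#' Build the county adjacency graph
#'
#' Reads a two-column edge list of county ids, symmetrizes it, restricts it
#' to the counties present in the panel, and computes connected components.
#'
#' @param edge_list Two-column data frame of county-id pairs, or path to a
#'   comma-delimited file.
#' @param panel The `coa_panel` whose counties the graph must cover.
#' @return An object of class `adjacency_graph` with elements `n_nodes`,
#'   `node_ids`, `edges` (two-column integer matrix of node indices, i <
#'   j), `components` (integer membership vector), `n_components`, and
#'   `isolated` (ids of counties with no neighbour).
#' @export
build_adjacency <- function(edge_list, panel) {
  if (is.character(edge_list)) {
    edge_list <- utils::read.csv(edge_list, stringsAsFactors = FALSE)
  }
  stopifnot(ncol(edge_list) >= 2)
  a <- as.character(edge_list[[1]])
  b <- as.character(edge_list[[2]])
  if (any(a == b)) {
    stop("self-loop edge(s) for county id(s): ",
         paste(utils::head(unique(a[a == b]), 5), collapse = ", "),
         call. = FALSE)
  }
  node_ids <- names(panel$county_index)
  unknown <- setdiff(unique(c(a, b)), node_ids)
  if (length(unknown) > 0) {
    stop("edge references unknown county id(s): ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  ia <- panel$county_index[a]
  ib <- panel$county_index[b]
  lo <- pmin(ia, ib); hi <- pmax(ia, ib)
  edges <- unique(cbind(lo, hi))
  dimnames(edges) <- list(NULL, c("i", "j"))
  g <- igraph::make_empty_graph(n = length(node_ids), directed = FALSE)
  g <- igraph::add_edges(g, as.vector(t(edges)))
  comp <- igraph::components(g)
  deg <- igraph::degree(g)
  structure(
    list(n_nodes = length(node_ids),
         node_ids = node_ids,
         edges = edges,
         components = comp$membership,
         n_components = comp$no,
         isolated = node_ids[deg == 0]),
    class = "adjacency_graph")
}

#' Restrict an adjacency graph to the counties of a panel
#'
#' Drops nodes (and their edges) for counties no longer present, e.g.
#' after the minimum-cropland filter, and recomputes components. A county
#' left with no neighbour forms its own component; the sum-to-zero
#' constraint then pins its intrinsic effect to zero, so such counties
#' are carried by the exchangeable county intercept instead.
#'
#' @param graph An `adjacency_graph`.
#' @param panel The filtered `coa_panel`.
#' @return An `adjacency_graph` over exactly the panel's counties.
#' @export
restrict_graph <- function(graph, panel) {
  ids <- names(panel$county_index)
  from <- graph$node_ids[graph$edges[, 1]]
  to <- graph$node_ids[graph$edges[, 2]]
  keep <- from %in% ids & to %in% ids
  build_adjacency(data.frame(from = from[keep], to = to[keep],
                             stringsAsFactors = FALSE), panel)
}

#' @export
print.adjacency_graph <- function(x, ...) {
  cat(sprintf("adjacency_graph: %d nodes, %d edges, %d component(s)\n",
              x$n_nodes, nrow(x$edges), x$n_components))
  invisible(x)
}
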