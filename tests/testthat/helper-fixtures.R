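# Programmatic fixtures shared across test files. Everything is built in
# code; nothing is read from disk except files the tests write themselves.

# A tiny hand-written panel: 3 counties x 4 years, two states.
toy_records <- function() {
  grid <- expand.grid(county_id = c("A", "B", "C"),
                      year = c(1997L, 2002L, 2007L, 2012L),
                      stringsAsFactors = FALSE)
  n <- nrow(grid)
  set.seed(42)
  data.frame(
    county_id = grid$county_id,
    state_id = ifelse(grid$county_id == "C", "s2", "s1"),
    year = grid$year,
    y = round(runif(n, 0.1, 0.4), 3),
    x_corn = round(runif(n, 0.05, 0.3), 3),
    x_cov = round(runif(n, 0.01, 0.2), 3),
    x_sw = round(runif(n, 0.05, 0.3), 3),
    x_income = round(runif(n, 0.2, 1.2), 3),
    x_size = round(runif(n, 0.5, 2), 3),
    x_gdd = round(runif(n, 1, 5), 3),
    x_crop = round(runif(n, 0.05, 0.6), 3),
    stringsAsFactors = FALSE)
}

toy_panel <- function() {
  coa_panel(toy_records(),
            centroids = data.frame(county_id = c("A", "B", "C"),
                                   x_km = c(0, 1, 2), y_km = c(0, 0, 1)))
}

# Write a toy panel CSV and return the path.
toy_panel_csv <- function(records = toy_records(), path = tempfile(fileext = ".csv")) {
  write.csv(records, path, row.names = FALSE, quote = FALSE, na = "")
  path
}

# Small simulated lattice panel, cached per (rows, cols, seed, model).
.sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(rows = 8, cols = 8, seed = 1, model = 6,
                       censor = FALSE) {
  key <- paste(rows, cols, seed, model, censor, sep = "_")
  if (is.null(.sim_cache[[key]])) {
    cfg <- sim_config(grid_rows = rows, grid_cols = cols, seed = seed,
                      generative_model = model)
    .sim_cache[[key]] <- simulate_panel(cfg, censor = censor)
  }
  .sim_cache[[key]]
}

# Moran's I on a lattice field (independent check of spatial structure).
morans_i <- function(x, graph) {
  e <- graph$edges
  xc <- x - mean(x)
  num <- sum(xc[e[, 1]] * xc[e[, 2]]) * 2
  w_total <- 2 * nrow(e)
  (length(x) / w_total) * num / sum(xc^2)
}
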