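test_that("read_panel performs an identity read and preserves row order", {
  rec <- toy_records()
  path <- toy_panel_csv(rec)
  panel <- read_panel(path)
  expect_s3_class(panel, "coa_panel")
  expect_equal(n_records(panel), nrow(rec))
  expect_equal(panel$records$county_id, rec$county_id)
  expect_equal(panel$records$y, rec$y)
  expect_false(any(panel$censored))
})

test_that("read_panel flags sentinel entries as censored", {
  rec <- toy_records()
  rec$x_income[3] <- ""
  path <- toy_panel_csv(rec)
  panel <- read_panel(path)
  expect_true(panel$censored[3, "x_income"])
  expect_true(is.na(panel$records$x_income[3]))
  expect_equal(sum(panel$censored), 1)
})

test_that("read_panel errors name the missing column and bad rows", {
  rec <- toy_records()
  rec$y <- NULL
  expect_error(read_panel(toy_panel_csv(rec)), "missing column.*y")
  rec2 <- toy_records()
  rec2$x_size[5] <- "oops"
  expect_error(read_panel(toy_panel_csv(rec2)), "x_size.*5")
})

test_that("write_panel round-trips finite decimals bit-for-bit", {
  panel <- read_panel(toy_panel_csv())
  out <- tempfile(fileext = ".csv")
  write_panel(panel, out)
  back <- read_panel(out)
  for (f in c("y", panel_covariates())) {
    expect_identical(back$records[[f]], panel$records[[f]])
  }
})

test_that("impute_censored uses the county mean of observed years", {
  rec <- toy_records()
  rec$x_crop[rec$county_id == "A"] <- c(0.2, NA, 0.3, 0.1)[order(order(
    rec$year[rec$county_id == "A"]))]
  # enforce exact values by year order
  rows <- which(rec$county_id == "A")
  rec$x_crop[rows[order(rec$year[rows])]] <- c(0.2, NA, 0.3, 0.1)
  path <- toy_panel_csv(rec)
  panel <- impute_censored(read_panel(path))
  got <- panel$records$x_crop[panel$records$county_id == "A" &
                                panel$records$year == 2002]
  expect_equal(got, mean(c(0.2, 0.3, 0.1)))
  expect_false(any(panel$censored))
})

test_that("a county censored in every year is imputed to zero", {
  rec <- toy_records()
  rec$x_income[rec$county_id == "B"] <- NA
  panel <- impute_censored(read_panel(toy_panel_csv(rec)))
  expect_equal(panel$records$x_income[panel$records$county_id == "B"],
               rep(0, 4))
  expect_true(all(panel$imputation_report$zero_fallback[
    panel$imputation_report$county_id == "B"]))
})

test_that("imputation leaves a fully observed panel unchanged", {
  panel <- read_panel(toy_panel_csv())
  imputed <- impute_censored(panel)
  expect_equal(imputed$records, panel$records)
})

test_that("the cropland filter is strictly less-than and reports removals", {
  rec <- toy_records()
  rec$x_crop[rec$county_id == "A"] <- 0.01
  rec$x_crop[rec$county_id == "B"] <- 0.03
  rec$x_crop[rec$county_id == "C"] <- 0.50
  panel <- impute_censored(read_panel(toy_panel_csv(rec)))
  kept <- filter_min_cropland(panel)
  expect_setequal(unique(kept$records$county_id), c("B", "C"))
  expect_equal(kept$removal_report$dropped_counties, "A")
  expect_equal(kept$removal_report$n_records_removed, 4)
  expect_error(filter_min_cropland(panel, threshold = 1.5), "threshold")
})

test_that("threshold zero is the identity filter", {
  panel <- impute_censored(read_panel(toy_panel_csv()))
  kept <- filter_min_cropland(panel, threshold = 0)
  expect_equal(n_records(kept), n_records(panel))
})

test_that("county-level and record-level filter scopes differ as designed", {
  # county A is below threshold in 1 of 4 years
  rec <- toy_records()
  rec$x_crop[rec$county_id == "A"] <- c(0.5, 0.5, 0.5, 0.5)
  rows <- which(rec$county_id == "A")
  rec$x_crop[rows[rec$year[rows] == 1997]] <- 0.02
  rec$x_crop[rec$county_id %in% c("B", "C")] <- 0.4
  panel <- impute_censored(read_panel(toy_panel_csv(rec)))
  # county scope: mean x_crop for A = (0.02+1.5)/4 = 0.38 >= 0.03, so A stays
  expect_equal(n_records(filter_min_cropland(panel, scope = "county")), 12)
  # record scope: only the single low county-year is dropped
  by_record <- filter_min_cropland(panel, scope = "record")
  expect_equal(n_records(by_record), 11)
  expect_false(any(by_record$records$county_id == "A" &
                     by_record$records$year == 1997))
  # and a county whose mean is below the threshold goes entirely under
  # county scope even if one year is fine
  rec2 <- toy_records()
  rec2$x_crop[rec2$county_id == "A"] <- c(0.01, 0.01, 0.01, 0.08)
  rec2$x_crop[rec2$county_id %in% c("B", "C")] <- 0.4
  panel2 <- impute_censored(read_panel(toy_panel_csv(rec2)))
  expect_setequal(
    unique(filter_min_cropland(panel2, scope = "county")$records$county_id),
    c("B", "C"))
})

test_that("centering zeroes covariate means, stores them, and leaves y alone", {
  panel <- impute_censored(read_panel(toy_panel_csv()))
  y_before <- panel$records$y
  centered <- center_covariates(panel)
  for (f in panel_covariates()) {
    expect_lt(abs(mean(centered$records[[f]])), 1e-10)
  }
  expect_identical(centered$records$y, y_before)
  expect_equal(centered$covariate_means[["x_crop"]],
               mean(panel$records$x_crop))
  # idempotence: second pass subtracts zero
  twice <- center_covariates(centered)
  expect_equal(twice$records[, panel_covariates()],
               centered$records[, panel_covariates()])
  expect_equal(twice$covariate_means, centered$covariate_means)
})

test_that("centering a simple column gives the textbook answer", {
  rec <- toy_records()[1:3, ]
  rec$county_id <- c("A", "B", "C")
  rec$year <- 1997L
  rec$x_gdd <- c(1, 2, 3)
  panel <- coa_panel(rec, years = c(1997L, 2002L, 2007L, 2012L))
  centered <- center_covariates(panel)
  expect_equal(centered$records$x_gdd, c(-1, 0, 1))
  expect_equal(centered$covariate_means[["x_gdd"]], 2)
})

test_that("the pipeline equals impute -> filter -> center run in sequence", {
  rec <- toy_records()
  rec$x_income[2] <- NA
  rec$x_crop[rec$county_id == "A"] <- 0.01
  path <- toy_panel_csv(rec)
  a <- preprocess_panel(read_panel(path))
  b <- center_covariates(filter_min_cropland(impute_censored(
    read_panel(path))))
  expect_equal(a$records, b$records)
  expect_equal(a$covariate_means, b$covariate_means)
})

test_that("adjacency building symmetrizes, deduplicates, and finds components", {
  panel <- toy_panel()
  g <- build_adjacency(data.frame(from = c("A", "B", "B"),
                                  to = c("B", "A", "C")), panel)
  expect_equal(nrow(g$edges), 2)
  expect_equal(g$n_components, 1)
  g2 <- build_adjacency(data.frame(from = "A", to = "B"), panel)
  expect_equal(g2$n_components, 2)
  expect_equal(g2$isolated, "C")
})

test_that("adjacency rejects self-loops and unknown counties", {
  panel <- toy_panel()
  expect_error(build_adjacency(data.frame(from = "A", to = "A"), panel),
               "self-loop")
  expect_error(build_adjacency(data.frame(from = "A", to = "Z"), panel),
               "unknown county.*Z")
})

test_that("restrict_graph trims nodes and recomputes components", {
  sim <- cached_sim(rows = 3, cols = 3)
  panel <- sim$panel
  # drop one corner county
  keep <- panel$records$county_id != "c0001"
  smaller <- coa_panel(panel$records[keep, ],
                       centroids = sim$lattice$centroids[-1, ],
                       censored = panel$censored[keep, ],
                       years = panel$years)
  g <- restrict_graph(sim$graph, smaller)
  expect_equal(g$n_nodes, 8)
  expect_equal(g$n_components, 1)
  expect_false("c0001" %in% g$node_ids)
})

test_that("duplicate county-years are rejected", {
  rec <- toy_records()
  rec$year[2] <- rec$year[1]
  rec$county_id[2] <- rec$county_id[1]
  expect_error(coa_panel(rec), "duplicate")
})
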