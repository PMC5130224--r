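#!/usr/bin/env Rscript
# Step 1: generate the synthetic county-lattice panel used throughout the
# workflow. A 20x20 rook lattice (400 "counties" in square-block
# "states") observed over the four census years, with spatially smooth
# covariates, a response drawn from the space-time latent Gaussian model
# at the published posterior means, and 5% random covariate suppression.
# Writes panel/edges/centroids CSVs under results/data/.

suppressMessages(library(insectscape))

cfg <- sim_config(seed = 20160901)
sim <- simulate_panel(cfg)
write_simulated_data(sim, "results/data")

rec <- sim$panel$records
message(sprintf("simulated %d county-years (%d counties x %d years)",
                nrow(rec), n_counties(sim$panel), length(cfg$years)))
message(sprintf("censored covariate entries: %d (%.1f%%)",
                sum(sim$panel$censored),
                100 * mean(sim$panel$censored[, panel_covariates()])))
message(sprintf("response y: mean %.3f, range [%.3f, %.3f]",
                mean(rec$y), min(rec$y), max(rec$y)))
message("wrote results/data/{panel,edges,centroids}.csv")
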