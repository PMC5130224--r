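#!/usr/bin/env Rscript
# Step 2: read the panel back from disk and run the canonical
# preprocessing: impute censored entries (county mean across censuses,
# zero when a county is censored throughout), drop counties with less
# than 3% of county land in harvested cropland, centre the covariates.
# Writes the preprocessed panel and the imputation/removal reports.

suppressMessages(library(insectscape))

panel <- read_panel("results/data/panel.csv",
                    centroids = "results/data/centroids.csv")
message(sprintf("read %d records, %d censored entries",
                n_records(panel), sum(panel$censored)))

imputed <- impute_censored(panel)
write.csv(imputed$imputation_report, "results/imputation_report.csv",
          row.names = FALSE)
message(sprintf("imputed %d entries (%d by the zero fallback)",
                sum(imputed$imputation_report$n_imputed),
                sum(imputed$imputation_report$n_imputed[
                  imputed$imputation_report$zero_fallback])))

filtered <- filter_min_cropland(imputed)
rm_rep <- filtered$removal_report
write.csv(rm_rep$removed, "results/removal_report.csv", row.names = FALSE)
message(sprintf("3%% cropland filter removed %d counties (%d records)",
                length(rm_rep$dropped_counties), rm_rep$n_records_removed))

centered <- center_covariates(filtered)
write_panel(centered, "results/panel_preprocessed.csv")
write.csv(data.frame(covariate = names(centered$covariate_means),
                     grand_mean = as.numeric(centered$covariate_means)),
          "results/covariate_means.csv", row.names = FALSE)
message("covariate grand means at centering:")
for (f in names(centered$covariate_means)) {
  message(sprintf("  %-9s %8.4f", f, centered$covariate_means[[f]]))
}
message("wrote results/panel_preprocessed.csv")
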