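#!/usr/bin/env Rscript
# Step 5: interpretive quantities from the DIC-best fit: effect
# translations on the response scale, standardized coefficients, and (if
# a spatially-varying-slope fit is present) the per-county cropland
# coefficients.

suppressMessages(library(insectscape))

fits <- readRDS("scratch/fits.rds")
panel <- read_panel("results/data/panel.csv",
                    centroids = "results/data/centroids.csv")
pp <- preprocess_panel(panel)

best_nm <- names(fits)[which.min(sapply(fits, `[[`, "dic"))]
best <- fits[[best_nm]]
message("DIC-best model: ", best_nm)

s <- posterior_summary(best)
slope <- function(term) s$mean[s$term == term]
contrasts <- data.frame(
  covariate = c("x_corn", "x_cov", "x_sw", "x_crop", "year"),
  from = c(0.40, 0.10, 0.40, 0.20, 0),
  to = c(0.80, 0.30, 0.80, 0.80, 15))
contrasts$slope <- vapply(contrasts$covariate, slope, numeric(1))
contrasts$implied_change <- mapply(effect_translation, contrasts$slope,
                                   contrasts$from, contrasts$to)
write.csv(contrasts, "results/effect_translations.csv", row.names = FALSE)
message("implied changes in relative insecticide use:")
for (i in seq_len(nrow(contrasts))) {
  message(sprintf("  %-7s %.2f -> %.2f : %+0.2f", contrasts$covariate[i],
                  contrasts$from[i], contrasts$to[i],
                  contrasts$implied_change[i]))
}

std <- standardized_coefficients(best, pp)
write.csv(std, "results/standardized_coefficients.csv", row.names = FALSE)
message("standardized coefficients (slope x covariate SD):")
for (i in seq_len(nrow(std))) {
  message(sprintf("  %-9s raw %+0.3f  standardized %+0.3f",
                  std$covariate[i], std$slope[i], std$standardized[i]))
}

if ("model_5" %in% names(fits)) {
  svc <- svc_coefficients(fits$model_5, pp)
  write.csv(svc, "results/svc_cropland.csv", row.names = FALSE)
  message(sprintf(
    "spatially varying cropland slopes: mean %.3f, range [%.3f, %.3f]",
    mean(svc$svc), min(svc$svc), max(svc$svc)))
}
message("wrote results/effect_translations.csv and friends")
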