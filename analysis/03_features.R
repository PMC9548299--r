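#!/usr/bin/env Rscript
# Stage 3: extract the cardiorespiratory predictors in 30-min windows with
# 50% overlap for both splits: vital-sign means/SDs, pairwise
# cross-correlations, SDNN, COSEn and the DFA variance slope. Missing
# features are imputed with the development-cohort medians. Writes
# results/features_{development,validation}.csv and results/medians.csv.

suppressPackageStartupMessages(library(ventrisk))

cfg <- load_config("analysis/config.yaml")
rules <- do.call(epoch_rules, cfg$epochs)
fp <- do.call(feature_params, cfg$features)

feats <- lapply(c("development", "validation"), function(split) {
  cohort <- read_cohort(file.path("results", "data", split))
  cohort_features(cohort, fp, rules)
})
names(feats) <- c("development", "validation")

med <- feature_medians(feats$development)
readr::write_csv(
  tibble::tibble(feature = names(med), median = unname(med)),
  "results/medians.csv"
)

for (split in names(feats)) {
  imp <- impute_missing(feats[[split]], med)
  readr::write_csv(imp, sprintf("results/features_%s.csv", split), na = "")
  miss <- colMeans(as.matrix(imp[paste0(feature_names(), "_imputed")]))
  cat(sprintf(
    "%s: %d uncensored 15-min epochs, %d features; most-missing feature %s (%.1f%% imputed)\n",
    split, nrow(imp), length(feature_names()),
    sub("_imputed$", "", names(which.max(miss))), 100 * max(miss)
  ))
}
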