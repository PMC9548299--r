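#!/usr/bin/env Rscript
# Stage 1: simulate the synthetic ICU cohorts.
#
# Generates a development cohort (used only to fit the risk models and to
# define imputation medians) and an independent validation cohort, and
# writes both as delimited tables under results/data/.

suppressPackageStartupMessages(library(ventrisk))

cfg <- load_config("analysis/config.yaml")

for (split in c("development", "validation")) {
  stage <- if (split == "development") "simulate_dev" else "simulate_val"
  args <- cfg$cohort
  args$seed <- stage_seed(cfg$seed, stage)
  cohort <- generate_cohort(do.call(cohort_config, args))
  dir <- file.path("results", "data", split)
  write_cohort(cohort, dir)
  adm <- cohort_admissions(cohort)
  cat(sprintf(
    "%s: %d admissions (%d events, %d DNI), median stay %.1f h -> %s\n",
    split, nrow(adm), sum(!is.na(adm$event_time_min)), sum(adm$dni),
    median(adm$duration_min) / 60, dir
  ))
}
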