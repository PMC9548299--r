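#!/usr/bin/env Rscript
# Stage 2: reconstruct mechanical-ventilation epochs from the ventilator
# respiratory-rate flowsheet entries, reconcile them with the known
# emergent-intubation times, and derive the censoring mask on the 15-min
# epoch grid. Writes results/epochs.csv and results/censor.csv for the
# validation split and reports how much monitoring time is censored.

suppressPackageStartupMessages(library(ventrisk))

cfg <- load_config("analysis/config.yaml")
rules <- do.call(epoch_rules, cfg$epochs)
fp <- do.call(feature_params, cfg$features)
cohort <- read_cohort("results/data/validation")

epochs <- list()
censor <- list()
for (rec in cohort) {
  ep <- build_epochs(rec$flowsheet, rules)
  ep <- split_at_intubation(ep, rec$flowsheet, rec$event_times_min, rules,
                            admission_end = rec$duration_min)
  grid <- iter_windows(0, rec$duration_min, fp)
  censor[[rec$admission_id]] <- tibble::tibble(
    admission_id = rec$admission_id,
    t_min = grid$end_min,
    censored = censor_mask(grid$end_min, ep, dni = rec$dni)
  )
  if (nrow(ep)) {
    epochs[[rec$admission_id]] <-
      tibble::add_column(ep, admission_id = rec$admission_id, .before = 1)
  }
}
epochs <- do.call(rbind, epochs)
censor <- do.call(rbind, censor)
readr::write_csv(epochs, "results/epochs.csv", na = "")
readr::write_csv(censor, "results/censor.csv", na = "")

cat(sprintf(
  "reconstructed %d ventilation epochs across %d admissions; %.1f%% of %d 15-min epochs censored (ventilated or DNI)\n",
  nrow(epochs), length(unique(epochs$admission_id)),
  100 * mean(censor$censored), nrow(censor)
))
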