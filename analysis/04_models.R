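#!/usr/bin/env Rscript
# Stage 4: fit the three logistic risk models on the development split and
# score the validation split. The vital-signs model uses linear predictor
# relationships at a 24 h horizon; the two spline models use restricted
# cubic splines at 4 h (MICU) and 6 h (SICU) horizons. Predicted event
# probabilities are divided by the development-set mean to yield relative
# risk. Writes results/model_<name>.json and results/risk_<name>.csv.

suppressPackageStartupMessages(library(ventrisk))

cfg <- load_config("analysis/config.yaml")
dev_feat <- readr::read_csv("results/features_development.csv",
                            show_col_types = FALSE)
val_feat <- readr::read_csv("results/features_validation.csv",
                            show_col_types = FALSE)
dev_adm <- readr::read_csv("results/data/development/admissions.csv",
                           show_col_types = FALSE)

for (spec in default_model_specs()[cfg$models]) {
  labels <- features_labels(dev_feat, dev_adm, spec$horizon_hours)
  model <- fit_model(dev_feat, labels, spec)
  risk <- predict_relative_risk(model, val_feat,
                                cap = cfg$evaluation$risk_cap)
  readr::write_csv(risk, sprintf("results/risk_%s.csv", spec$name), na = "")
  jsonlite::write_json(
    list(spec = unclass(model$spec), coefficients = as.list(model$coefficients),
         knots = model$knots, train_mean_p = model$train_mean_p,
         method = model$method),
    sprintf("results/model_%s.json", spec$name),
    auto_unbox = TRUE, digits = NA
  )
  cat(sprintf(
    "%s (%s basis, %g h horizon): %d development positives (%.1f%%), train mean p %.4f, validation relative risk range %.2f-%.1f\n",
    spec$name, spec$basis, spec$horizon_hours, sum(labels),
    100 * mean(labels), model$train_mean_p,
    min(risk$relative_risk), max(risk$relative_risk)
  ))
}
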