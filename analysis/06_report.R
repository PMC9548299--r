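#!/usr/bin/env Rscript
# Stage 6: assemble the run report and figures from the evaluation tables:
# events-with-data versus lead time, the mean risk trajectories, the
# AUC-versus-window curves, and the calibration plots. Figures go to
# results/figures/ (PDF); the plain-text summary to results/report.txt.

suppressPackageStartupMessages({
  library(ventrisk)
  library(ggplot2)
})

cfg <- load_config("analysis/config.yaml")
dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)

tabs <- lapply(cfg$models, function(nm) {
  list(
    name = nm,
    traj = readr::read_csv(sprintf("results/trajectory_%s.csv", nm),
                           show_col_types = FALSE),
    auc = readr::read_csv(sprintf("results/auc_curve_%s.csv", nm),
                          show_col_types = FALSE),
    cal = readr::read_csv(sprintf("results/calibration_%s.csv", nm),
                          show_col_types = FALSE)
  )
})

traj_all <- do.call(rbind, lapply(tabs, function(t) {
  tibble::add_column(t$traj, model = t$name, .before = 1)
}))

# events with monitoring data as a function of lead time
p <- ggplot(traj_all, aes(-offset_min / 60, n, colour = model)) +
  geom_step() +
  labs(x = "hours before emergent intubation", y = "events with data")
ggsave("results/figures/leadtime.pdf", p, width = 6, height = 4)

p <- ggplot(traj_all, aes(offset_min / 60, mean)) +
  geom_ribbon(aes(ymin = ci_low, ymax = ci_high), fill = "grey80") +
  geom_line() +
  geom_point(data = subset(traj_all, !is.na(p_value) & p_value < 0.05),
             colour = "white", fill = "black", shape = 21, size = 1.2) +
  facet_wrap(~model, scales = "free_y") +
  labs(x = "hours relative to emergent intubation", y = "mean relative risk")
ggsave("results/figures/trajectory.pdf", p, width = 9, height = 3.5)

auc_all <- do.call(rbind, lapply(tabs, function(t) {
  tibble::add_column(t$auc, model = t$name, .before = 1)
}))
p <- ggplot(auc_all, aes(window_hours, auc, colour = model)) +
  geom_pointrange(aes(ymin = ci_low, ymax = ci_high),
                  position = position_dodge(width = 0.8)) +
  labs(x = "event window before intubation (h)", y = "AUC")
ggsave("results/figures/auc_vs_window.pdf", p, width = 6, height = 4)

cal_all <- do.call(rbind, lapply(tabs, function(t) {
  tibble::add_column(t$cal, model = t$name, .before = 1)
}))
p <- ggplot(cal_all, aes(mean_predicted_rr, observed_rr, colour = model)) +
  geom_abline(linetype = "dashed") +
  geom_point() +
  labs(x = "predicted relative risk (decile mean)",
       y = "observed relative risk")
ggsave("results/figures/calibration.pdf", p, width = 6, height = 4)

censor <- readr::read_csv("results/censor.csv", show_col_types = FALSE)
n_epochs <- sum(!censor$censored) * length(cfg$models)
lines <- c(
  "Synthetic external-validation run",
  sprintf("seed: %d", cfg$seed),
  sprintf("censored 15-min epochs: %.1f%%", 100 * mean(censor$censored)),
  sprintf("risk estimates computed: %d epochs = %.2f patient-years",
          n_epochs, monitored_patient_years(n_epochs, 15)),
  vapply(tabs, function(t) {
    sig <- t$traj$offset_min[!is.na(t$traj$p_value) & t$traj$p_value < 0.05]
    sprintf("%s: AUC %.3f-%.3f; early warning from %.1f h pre-event",
            t$name, min(t$auc$auc), max(t$auc$auc),
            if (length(sig)) -min(sig) / 60 else NA_real_)
  }, character(1))
)
writeLines(lines, "results/report.txt")
cat(lines, sep = "\n")
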