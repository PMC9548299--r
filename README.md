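# ventrisk

Validation tooling for continuous-monitoring risk models of respiratory
failure leading to emergent intubation in ICU patients.

Unplanned (emergent) intubation is a high-mortality event that is often
preceded by hours of slowly progressive physiological deterioration.
Risk models built solely on continuous cardiorespiratory monitoring data
— windowed vital-sign statistics and heart-rate-variability measures fed
into logistic regressions — can surface that deterioration as a rising
bedside risk estimate. Validating such models needs a substantial
scaffold: reconstructing when patients were already ventilated (so those
epochs can be censored), extracting the model predictors on a fine time
grid, and evaluating discrimination, calibration and lead time in ways
that respect within-admission correlation.

`ventrisk` implements that scaffold end to end for researchers in
physiologic predictive monitoring, together with a synthetic ICU cohort
generator so every stage is testable without access to protected patient
data:

* **Synthetic cohorts** — admissions with AR(1) vital signs at 1/min,
  beat-to-beat RR intervals, a smooth multi-hour pre-intubation
  deterioration for event admissions (rising heart/respiratory rate,
  falling SpO2 and blood pressure, shrinking RR-interval variability),
  sparse ventilator flowsheet documentation, DNI admissions, and ground
  truth for every quantity downstream stages must recover.
* **Ventilation epochs** — mechanical ventilation reconstructed from
  ventilator respiratory-rate flowsheet entries: entries gapped by more
  than 16 h split epochs, isolated entries open 1 h epochs, and known
  emergent-intubation times re-anchor epoch boundaries (extubation at the
  preceding entry, intubation exactly at the event).
* **Features** — computed in 30-min windows with 50% overlap: per-channel
  means and SDs, pairwise zero-lag cross-correlations, SDNN, the
  coefficient of sample entropy `COSEn = SampEn(m, r) + ln(2r) − ln(μ_RR)`,
  and the detrended-fluctuation-analysis variance slope (slope of
  `log F²(n)` vs `log n`; ≈1 for white noise). Missing features are
  imputed with development-cohort medians.
* **Risk models** — binary logistic regressions with linear
  (24 h horizon) or restricted-cubic-spline bases (4 h MICU, 6 h SICU
  horizons), optional AIC forward-stepwise selection, and relative-risk
  output: predicted probability divided by the development-set mean, a
  fold-increase with mean 1 on the development data.
* **Evaluation** — event-aligned mean risk trajectories with 95% ribbons,
  one-sided Wilcoxon signed-rank tests against the same admission 12 h
  earlier (exact null by midrank dynamic programming up to 25 pairs),
  AUC as a function of the 4–24 h event window with percentile CIs from a
  200-run bootstrap resampled by hospital admission, and decile
  calibration against observed risk in a 12 h detection window.

## Worked example

The analysis is organised as numbered stage drivers over the package:

```sh
Rscript analysis/01_simulate.R   # synthetic development + validation cohorts
Rscript analysis/02_epochs.R    # ventilation epochs and censoring
Rscript analysis/03_features.R  # windowed predictors + median imputation
Rscript analysis/04_models.R    # fit the three risk models, score validation
Rscript analysis/05_evaluate.R  # trajectories, AUC curves, calibration
Rscript analysis/06_report.R    # tables, figures, run report
```

With the checked-in `analysis/config.yaml` (80 admissions per split,
30% event fraction, seed 20260917) the run prints, among others:

```
reconstructed 24 ventilation epochs across 24 admissions; 11.7% of 13643 15-min epochs censored (ventilated or DNI)
politano (linear basis, 24 h horizon): 2304 development positives (20.4%), train mean p 0.2042, validation relative risk range 0.05-4.9
politano: AUC 1.000 (4 h window) to 0.710 (24 h); risk significantly above 12-h-prior from 20.2 h pre-event; top calibration decile predicted 4.2 vs observed 4.2
moss_micu: AUC 0.993 (4 h window) to 0.600 (24 h); risk significantly above 12-h-prior from 5.2 h pre-event; top calibration decile predicted 10.4 vs observed 10.9
```

Read: about 12% of monitored 15-min epochs fall inside reconstructed
ventilation (or DNI admissions) and are censored; each model's relative
risk averages 1 on its development split by construction; discrimination
is near-perfect for epochs within 4 h of intubation and decays as the
event window widens to 24 h (the positive class then includes epochs up
to a day before the event, where the programmed deterioration has barely
started); the signed-rank test flags a significant rise over the
12-h-prior baseline hours before the event; and decile calibration sits
on the identity line because the validation cohort is drawn from the
same world the models were fit on. The same quantities can be computed
in one call with `run_pipeline(default_run_config(seed = 1))`.

Equivalently, from R:

```r
library(ventrisk)
art <- run_pipeline(default_run_config(seed = 1))
art$evaluation$moss_micu$auc_curve
art$evaluation$moss_micu$trajectory
```

## Acceptance script

`scripts/acceptance.R` re-runs the package's full computation from
scratch — simulating development and validation cohorts, reconstructing
ventilation epochs, extracting features, fitting the three models and
running the complete evaluation suite — and writes its JSON result file:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The run report (censored fraction, patient-years of risk estimates, AUC
ranges and earliest significant pre-event rise per model) is printed to
stdout and written under the output directory.

## Repository layout

```
R/                  package implementation (all computation lives here)
src/                C++ kernel for sample-entropy template counting
analysis/           numbered stage drivers (the worked analysis)
scripts/acceptance.R
tests/testthat/     unit, property and acceptance suites
vignettes/          methods vignette (model, assumptions, design choices)
```
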