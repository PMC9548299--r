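---
title: "Validating continuous-monitoring risk models for emergent intubation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating continuous-monitoring risk models for emergent intubation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ventrisk)
```

## The problem

Respiratory failure leading to emergent (unplanned) intubation in the ICU
is typically preceded by hours of slowly progressive physiological
deterioration. Risk models driven purely by continuous cardiorespiratory
monitoring — vital signs from the bedside monitor and beat-to-beat RR
intervals — can report on that trajectory directly, without depending on
clinician-initiated measurements. `ventrisk` implements the full
validation scaffold such models need: reconstructing mechanical
ventilation from flowsheet surrogates so already-ventilated time can be
censored, extracting the predictors on a 15-minute grid, fitting the
model family, and evaluating lead time, discrimination and calibration
with admission-level uncertainty. Because real cohorts of this kind are
not publicly depositable, the package ships a synthetic cohort generator
with complete ground truth; the evaluation suite therefore validates the
*pipeline*, not any original model weights (which were never published
and are re-fit here on synthetic development data).

## Ventilation epochs from flowsheet documentation

Intubation and extubation times other than the adjudicated events are
unknown, so mechanical ventilation is inferred from respiratory-therapist
charting of the *ventilator respiratory rate*: an epoch spans the first
to the last entry of a group; a gap of consecutive entries **strictly
greater than 16 h** (`split_gap`) splits groups; an isolated entry opens
a 1 h epoch (`isolated_duration`). Known event times then re-anchor the
epochs: an event inside an epoch splits it, with extubation placed at the
latest entry before the event and intubation exactly at the event time.

Numerical conventions, chosen once:

* the 16 h comparison is strict (`> 16 h` splits, `<= 16 h` merges);
  whether a gap of exactly 16 h merges is not derivable from the rule's
  plain statement, and the strict reading was adopted;
* epoch membership is closed on both ends, so a 15-min epoch stamped
  exactly at an extubation time is still censored (conservative
  exclusion of ventilated data);
* when an event must split an epoch but no flowsheet entry lies between
  the epoch start and the event (e.g. two events back to back), the
  pre-event piece extends to the event itself — ties are broken toward
  *longer* censoring — and every verified event always begins an epoch
  at exactly its event time.

## Predictors

All predictors are computed in 30-minute windows advanced every
15 minutes (50% overlap) and stamped at the window end; windows whose
end falls in a ventilation epoch, and all windows of DNI admissions,
yield no rows. Windows are half-open `(start, end]` on the per-minute
vitals grid so consecutive windows tile the grid without double-counting
the boundary sample. A span of `t` minutes yields
`floor((t - 30)/15) + 1` windows; 24 h gives 95.

* **Vital-sign statistics** — per-channel sample mean and SD (n−1) over
  non-missing samples; missing when fewer than 10 samples
  (`min_samples_per_window`) are present.
* **Cross-correlations** — zero-lag Pearson correlation on the common
  per-minute grid, pairwise-complete. The lag structure of the original
  implementation is unpublished; zero-lag Pearson is this package's
  documented choice, with missing results when the overlap is short or a
  channel is constant.
* **SDNN** — sample SD of the RR intervals in the window; RR-derived
  features require 100 beats (`min_beats_per_window`).
* **COSEn** — `SampEn(m, r) + ln(2r) − ln(μ_RR)` with `m = 1`,
  `r = 30 ms` by default (`r` is not stated by the validated models'
  description; 30 ms is standard COSEn practice and is recorded in the
  feature parameters). `SampEn = −ln(A/B)` uses Chebyshev distance with
  self-matches excluded; `B` counts matching pairs among all `n − m + 1`
  templates of length `m` and `A` among the `n − m` templates of length
  `m + 1`, so a constant series has `A/B` slightly below 1 (edge
  templates) and SampEn slightly above 0. The `m = 1` path is an
  `O(n log n)` sweep (sorted first components, Fenwick tree over second
  components) verified exactly against exhaustive enumeration.
* **DFA variance slope** — the mean-subtracted intervals are integrated,
  cut into non-overlapping boxes of `n` beats (partitions taken from
  both ends and averaged), linearly detrended per box, giving the mean
  squared residual `F²(n)`. The reported statistic is the least-squares
  slope of `log F²(n)` on `log n` over box sizes {4, 8, 16, 32, 64}: the
  "variance versus scale" convention, whose white-noise reference value
  is 1.0 — exactly twice the conventional scaling exponent α ≈ 0.5.
  Because the original convention cannot be confirmed from its one-line
  description, `dfa_log_f2 = FALSE` switches to the `log F(n)` reading.
  Natural logarithms are used throughout.

Missing features are imputed with per-feature medians from the
development split (standing in for the original development-cohort
medians), and every imputation is flagged in a `*_imputed` column.

## Risk models

Three binary logistic regressions sharing the full 17-feature set (which
predictors entered each original model is specified only in prior work,
so "all computed features" is the default, configurable per model):

| model | basis | horizon |
|---|---|---|
| `politano` | linear | 24 h |
| `moss_micu` | restricted cubic splines | 4 h |
| `moss_sicu` | restricted cubic splines | 6 h |

An epoch is a positive iff its admission's event falls in
`(0, horizon]` after the window end — an epoch exactly at the event time
is a negative, as are all epochs of never-intubated patients and event
patients' epochs beyond the horizon. Splines are the standard
truncated-power restricted cubic basis (linear beyond the boundary
knots), 3 knots per feature at the 10th/50th/90th development
percentiles; a feature with degenerate quantiles falls back to linear.
Fitting is maximum likelihood (`glm.fit`); complete or quasi-complete
separation triggers a refit by IRLS with a weak ridge penalty
(`λ = 1e-6`, slopes only), flagged in the model's `method` field.
Optional forward-stepwise selection adds whole features (all their basis
columns) while the AIC improves; it is off by default. Predictions are
reported as *relative risk* — predicted probability over the
development-set mean predicted probability — so the development mean is
1 by construction; an optional cap bounds extreme fold-increases for
display.

## Evaluation

* **Event-aligned trajectories** — every-15-min relative risks of event
  admissions aligned to the event (time zero), snapped to the nearest
  grid offset. The ribbon is the normal-approximation 95% CI
  (`mean ± 1.96·SD/√n`); the original ribbon construction is unstated,
  and SEM was chosen as the simplest estimator whose width the tests can
  predict. Offsets with one admission report no CI.
* **Signed-rank lag tests** — at each offset, a one-sided (greater)
  Wilcoxon signed-rank test against the same admission 12 h earlier;
  zero differences are dropped (Wilcoxon convention), no multiplicity
  correction (matching the per-offset 0.05 rule), offsets with fewer
  than 5 non-zero pairs are untested. The null distribution is exact up
  to 25 pairs via dynamic programming over doubled midranks (handles
  ties exactly; verified against full 2ⁿ enumeration); beyond that the
  normal approximation with tie and continuity correction is used.
* **AUC versus event window** — for windows 4–24 h the Mann–Whitney AUC
  (ties ½) of relative risk against the window's labels, with percentile
  95% CIs from 200 bootstrap replicates drawn *by hospital admission*
  (all epochs of a sampled admission enter together, preserving
  within-patient correlation). Single-class replicates are redrawn and
  counted. The resampler is seeded; CIs are reproducible.
* **Decile calibration** — uncensored measurements ranked by predicted
  relative risk with a stable tie order (prediction, admission, time),
  cut into 10 equal-count groups; per decile the mean prediction is
  plotted against the observed relative risk, i.e. the fraction of
  measurements within 12 h of an event divided by the development mean
  probability. Perfect calibration is the identity line, and the
  decile-weighted mean of observed risks reproduces the overall observed
  relative risk exactly (a conservation identity the tests assert).

## The synthetic world

The generator emulates exactly the structure the analysis assumes, with
defaults fixed once:

* 200 admissions, 25% events (≥50 events for aligned averaging), 5% DNI;
  lognormal stays with median 48 h (floored at 26 h for event admissions
  so an event time can be drawn uniformly in `[24 h, stay]`);
* vitals at 1/min: AR(1) noise (coefficient 0.9, stationary SDs
  HR 6 bpm, RR 3 /min, SpO2 1.5%, SBP 8 mmHg) around per-admission
  baselines; baselines vary *between* admissions (SDs 10 bpm, 2.5 /min,
  1.5%, 12 mmHg around HR 85, RR 18, SpO2 96, SBP 120). The
  between-admission level is essential realism: with one shared baseline
  any mean shift is perfectly separable and predicted risks saturate,
  which no real cohort exhibits;
* event admissions ramp linearly over the final 12 h to shifts of
  +25 bpm, +12 /min, −8% SpO2, −15 mmHg (per-admission lognormal
  magnitude multiplier, SD 0.25), and their RR-interval SD shrinks to
  half its 40 ms baseline — reduced heart-rate variability and
  complexity before the event;
* RR intervals are Gaussian around a per-admission mean (750 ± 60 ms
  between admissions), floored at 200 ms, with beat times accumulated
  from the sampled intervals;
* ventilation truth starts exactly at the event and runs to the end of
  stay; flowsheet entries are charted at epoch boundaries and at
  uniform 1–6 h gaps inside epochs (documentation denser than the split
  threshold, so reconstruction can recover the truth); controls are
  never ventilated unless configured; 5% random per-channel vitals
  dropout exercises imputation; one event per admission by default, a
  second event behind `allow_multi_event`.

What the generator does **not** emulate: waveform-level artifact and
ectopy, circadian and treatment-induced rhythms, non-stationary control
dynamics (the AR(1) choice is a stand-in, not an inference about real
cohorts), admission-mix heterogeneity (units, demographics), and
documentation errors in the flowsheet. A green end-to-end test
establishes that the pipeline recovers programmed structure from data
with these statistics — not that the models would achieve comparable
performance on a real cohort.

## Numerical and testing choices

* Determinism: one global seed fans out to per-stage child seeds by a
  fixed arithmetic map (`stage_seed`), all below 2³¹; identical
  configuration and seed reproduce every table byte for byte.
* Degenerate inputs yield flagged missing values, not errors: too few
  beats, no entropy template matches, zero DFA fluctuation, constant
  channels in a correlation.
* RR intervals implying non-positive durations are floored at 200 ms and
  the count recorded on the returned series.
* The null-cohort acceptance check uses a *simultaneous* Monte-Carlo
  band: the 4–24 h windows and three models share one cohort draw, so
  per-window 95% intervals would jointly fail about a third of the time
  under a true null; the band is Bonferroni-adjusted across all
  window-model combinations using the bootstrap SE.
* The signal-cohort monotonicity check averages the aligned trajectory
  into 1 h bins over the final ramp and allows backslides up to 2% of
  the total rise plus a plateau at the risk ceiling (1/train-mean-p,
  where predictions saturate), requiring a better-than-2-fold overall
  rise; calibration self-consistency uses binomial bands
  Bonferroni-adjusted across the 10 deciles.
* Suite-scale runs use hundreds of admissions with shorter synthetic
  stays (median 30–40 h) than the default world so the complete test
  suite runs in minutes on one CPU; the structure of the world is
  unchanged.

## Known limitations

* The re-fit models validate the pipeline's functional forms, not the
  original (unpublished) coefficients; absolute performance numbers on
  synthetic data are not comparable to any real cohort's.
* Post-event, post-extubation epochs of event admissions re-enter the
  control pool (only ventilated/DNI time is excluded); this follows the
  labelling rule as stated but deserves sensitivity analysis on real
  data.
* No artifact/ectopy filtering of RR intervals and no spectral HRV
  measures; inputs are assumed to be clean beat-to-beat intervals.
* Tracheostomy handling beyond exclusion flags is out of scope (it
  required manual chart review in the motivating study design).
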