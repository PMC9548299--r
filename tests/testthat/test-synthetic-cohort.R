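test_that("cohort generation honours counts, empty case and determinism", {
  expect_length(generate_cohort(quick_config(n = 0)), 0)

  cfg <- quick_config(n = 100, seed = 7, event_fraction = 0.1)
  co <- generate_cohort(cfg)
  expect_length(co, 100)
  adm <- cohort_admissions(co)
  expect_identical(sum(!is.na(adm$event_time_min)), 10L)
  expect_identical(sum(adm$dni), 5L)

  co2 <- generate_cohort(quick_config(n = 100, seed = 7, event_fraction = 0.1))
  expect_identical(co, co2)

  # different seed differs
  co3 <- generate_cohort(quick_config(n = 100, seed = 8, event_fraction = 0.1))
  expect_false(identical(co, co3))
})

test_that("event admissions carry a valid event and ground-truth ventilation", {
  co <- generate_cohort(quick_config(n = 40, seed = 3, event_fraction = 0.4))
  for (rec in co) {
    expect_true(all(rec$vitals$t_min >= 0 & rec$vitals$t_min <= rec$duration_min))
    expect_true(all(diff(rec$rr_intervals$beat_time_min) > 0))
    if (!is.na(rec$event_time_min)) {
      expect_gt(rec$event_time_min, 24 * 60)
      expect_lte(rec$event_time_min, rec$duration_min)
      # ventilation truth starts exactly at the event
      expect_true(rec$event_time_min %in% rec$truth_vent_epochs$start_min)
    } else {
      expect_identical(nrow(rec$truth_vent_epochs), 0L)
    }
  }
})

test_that("vitals simulator: constant at zero noise, linear ramp, AR(1) memory", {
  base <- c(hr = 80, rr = 18, spo2 = 97, sbp = 120)
  nz <- c(hr = 0, rr = 0, spo2 = 0, sbp = 0)
  v <- simulate_vitals(120, base, NULL, ar = 0.5, noise_sd = nz, seed = 1)
  expect_true(all(v$hr == 80))
  expect_true(all(v$spo2 == 97))

  # linear ramp midpoint: +10 breaths/min at event over 12 h => +5 at -6 h
  det <- list(event_time_min = 24 * 60, ramp_hours = 12,
              effect = c(hr = 0, rr = 10, spo2 = 0, sbp = 0))
  v <- simulate_vitals(24 * 60, base, det, ar = 0, noise_sd = nz, seed = 1)
  expect_equal(v$rr[v$t_min == 18 * 60], 23)
  expect_equal(v$rr[v$t_min == 24 * 60], 28)
  expect_equal(v$rr[v$t_min == 12 * 60], 18)

  # lag-1 autocorrelation approx equals the AR coefficient
  sd2 <- c(hr = 2, rr = 0, spo2 = 0, sbp = 0)
  v <- simulate_vitals(2e4, base, NULL, ar = 0.9, noise_sd = sd2, seed = 42)
  ac <- stats::acf(v$hr, lag.max = 1, plot = FALSE)$acf[2]
  expect_lt(abs(ac - 0.9), 0.05)
  # stationary marginal SD matches the requested noise SD
  expect_lt(abs(sd(v$hr) - 2), 0.2)

  expect_error(simulate_vitals(100, base, NULL, 0.5, c(hr = -1, rr = 0, spo2 = 0, sbp = 0)),
               "noise_sd")
})

test_that("RR-interval simulator: degenerate variance, beat count, SD shrink", {
  rr <- simulate_rr_intervals(30, mean_rr = 1000, sd_rr = 0, seed = 1)
  expect_true(all(rr$rr_ms[-1] == 1000))
  expect_true(all(diff(rr$beat_time_min) > 0))
  # one beat per second for 30 min (first beat at t = 0)
  expect_lte(abs(nrow(rr) - 1801), 1)

  det <- list(event_time_min = 600, ramp_hours = 6, shrink = 0.5)
  rr <- simulate_rr_intervals(600, mean_rr = 800, sd_rr = 50,
                              deterioration = det, seed = 9)
  final <- rr$rr_ms[rr$beat_time_min > 570][-1]
  early <- rr$rr_ms[rr$beat_time_min <= 60][-1]
  expect_lt(abs(sd(final) - 25), 3)
  expect_lt(abs(sd(early) - 50), 4)

  expect_error(simulate_rr_intervals(10, mean_rr = -5, sd_rr = 1), "mean_rr")
})

test_that("flowsheet entries stay inside ventilation epochs with bounded gaps", {
  none <- simulate_flowsheet(tibble::tibble(start_min = numeric(),
                                            end_min = numeric()), seed = 2)
  expect_identical(nrow(none), 0L)

  ep <- tibble::tibble(start_min = 0, end_min = 600)
  fl <- simulate_flowsheet(ep, doc_interval = c(1, 2), seed = 5)
  expect_true(all(fl$t_min >= 0 & fl$t_min <= 600))
  expect_true(min(fl$t_min) == 0 && max(fl$t_min) == 600)
  expect_lte(max(diff(sort(fl$t_min))), 120)

  bad <- tibble::tibble(start_min = c(0, 100), end_min = c(200, 300))
  expect_error(simulate_flowsheet(bad, seed = 1), "overlap")
})

test_that("flowsheet -> epoch reconstruction round-trips the ground truth", {
  # documentation gaps (1-6 h) are far below the 16 h split threshold, so
  # reconstruction recovers each truth epoch exactly (boundary entries are
  # charted at the boundaries themselves)
  set.seed(31)
  for (case in 1:15) {
    n_ep <- sample(1:3, 1)
    starts <- sort(runif(n_ep, 0, 5000))
    ends <- starts + runif(n_ep, 120, 2000)
    ok <- c(TRUE, if (n_ep > 1) starts[-1] > head(ends, -1) + 16 * 60)
    if (!all(ok)) next
    truth <- tibble::tibble(start_min = starts, end_min = ends)
    fl <- simulate_flowsheet(truth, doc_interval = c(1, 6), seed = case)
    got <- build_epochs(fl, epoch_rules())
    expect_identical(nrow(got), n_ep)
    expect_equal(got$start_min, truth$start_min)
    expect_equal(got$end_min, truth$end_min)
  }
})
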