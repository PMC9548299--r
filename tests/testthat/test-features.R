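make_vitals <- function(t, hr, rr = NULL, spo2 = NULL, sbp = NULL) {
  n <- length(t)
  tibble::tibble(
    t_min = t, hr = hr,
    rr = if (is.null(rr)) rep(18, n) else rr,
    spo2 = if (is.null(spo2)) rep(97, n) else spo2,
    sbp = if (is.null(sbp)) rep(120, n) else sbp
  )
}

test_that("window grid is the 30-min/15-min overlap scheme", {
  p <- feature_params()
  w <- iter_windows(0, 60, p)
  expect_equal(w$end_min, c(30, 45, 60))
  expect_equal(w$start_min, c(0, 15, 30))

  expect_identical(nrow(iter_windows(0, 29, p)), 0L)

  w24 <- iter_windows(0, 24 * 60, p)
  expect_identical(nrow(w24), as.integer((24 * 60 - 30) / 15 + 1))
  expect_true(all(diff(w24$end_min) == 15))
})

test_that("windowed statistics: means, SDs, sampling behaviour", {
  p <- feature_params(min_samples_per_window = 2)
  v <- make_vitals(1:30, hr = rep(80, 30))
  s <- window_vitals_stats(v, c(0, 30), p)
  expect_equal(s[["hr_mean"]], 80)
  expect_equal(s[["hr_sd"]], 0)

  v <- make_vitals(1:2, hr = c(70, 90))
  s <- window_vitals_stats(v, c(0, 30), p)
  expect_equal(s[["hr_mean"]], 80)
  expect_equal(s[["hr_sd"]], 20 / sqrt(2), tolerance = 1e-12)

  # below the sample threshold -> missing, not unstable values
  p10 <- feature_params(min_samples_per_window = 10)
  expect_true(is.na(window_vitals_stats(v, c(0, 30), p10)[["hr_mean"]]))

  set.seed(1)
  v <- make_vitals(1:5000, hr = rnorm(5000, 80, 5))
  s <- window_vitals_stats(v, c(0, 5000), p)
  expect_lt(abs(s[["hr_mean"]] - 80), 0.3)
  expect_lt(abs(s[["hr_sd"]] - 5), 0.3)
})

test_that("cross-correlations are zero-lag Pearson with missing handling", {
  p <- feature_params(min_samples_per_window = 3)
  t <- 1:30
  x <- sin(t)
  v <- make_vitals(t, hr = x, rr = x)       # identical channels -> 1
  cc <- window_cross_correlations(v, c(0, 30), p)
  expect_equal(cc[["cc_hr_rr"]], 1)

  v <- make_vitals(t, hr = x, rr = 40 - x)  # exact negation -> -1
  cc <- window_cross_correlations(v, c(0, 30), p)
  expect_equal(cc[["cc_hr_rr"]], -1)

  # small printed pair set against the direct covariance formula
  hx <- c(62, 75, 81, 70, 68); hy <- c(14, 19, 23, 16, 18)
  v <- make_vitals(1:5, hr = hx, rr = hy)
  cc <- window_cross_correlations(v, c(0, 30), p)
  direct <- sum((hx - mean(hx)) * (hy - mean(hy))) /
    sqrt(sum((hx - mean(hx))^2) * sum((hy - mean(hy))^2))
  expect_equal(cc[["cc_hr_rr"]], direct, tolerance = 1e-12)

  # zero-variance channel -> missing; bounded in [-1, 1] on random inputs
  v <- make_vitals(1:10, hr = rep(80, 10), rr = rnorm(10))
  expect_true(is.na(window_cross_correlations(v, c(0, 30), p)[["cc_hr_rr"]]))
  set.seed(2)
  for (i in 1:20) {
    v <- make_vitals(1:20, hr = rnorm(20), rr = rnorm(20),
                     spo2 = runif(20), sbp = rexp(20))
    cc <- window_cross_correlations(v, c(0, 30), p)
    expect_true(all(abs(cc) <= 1 + 1e-12, na.rm = TRUE))
  }
})

test_that("sample entropy equals the exhaustive template-pair oracle", {
  # deterministic edge cases
  x <- rep(5, 30)
  cnt <- oracle_sampen_counts(x, 1, 0.2)
  expect_lt(cnt[["A"]], cnt[["B"]])  # edge templates make A/B < 1
  expect_equal(sample_entropy(x, 1, 0.2), oracle_sampen(x, 1, 0.2))
  expect_gt(sample_entropy(x, 1, 0.2), 0)

  # distinct spread-out values: no length-2 template matches -> missing
  expect_true(is.na(sample_entropy(c(1, 100, 2, 200, 3), m = 1, r = 1)))
  expect_true(is.na(sample_entropy(c(1, 2), m = 1, r = 1)))

  # exact equality with the O(N^2) enumeration on random series, N <= 200
  set.seed(99)
  for (i in 1:40) {
    n <- sample(10:200, 1)
    m <- sample(1:2, 1)
    x <- rnorm(n)
    r <- 0.2 * sd(x)
    got <- sample_entropy(x, m, r)
    want <- oracle_sampen(x, m, r)
    if (is.na(want)) expect_true(is.na(got)) else expect_equal(got, want)
  }
})

test_that("COSEn applies the entropy-rate corrections and is scale invariant", {
  set.seed(5)
  x <- rnorm(300, 1000, 50)
  r <- 30
  expect_equal(cosen(x, 1, r),
               sample_entropy(x, 1, r) + log(2 * r) - log(mean(x)),
               tolerance = 1e-12)
  # direct arithmetic of the correction terms: SampEn 0, r 30, mean 1000
  expect_equal(0 + log(60) - log(1000), -2.813, tolerance = 1e-3)

  # doubling r adds ln 2 minus the SampEn change
  d <- cosen(x, 1, 2 * r) - cosen(x, 1, r)
  d_se <- sample_entropy(x, 1, 2 * r) - sample_entropy(x, 1, r)
  expect_equal(d, log(2) + d_se, tolerance = 1e-12)

  # joint rescaling of intervals and tolerance leaves COSEn unchanged
  expect_equal(cosen(2 * x, 1, 2 * r), cosen(x, 1, r), tolerance = 1e-9)
})

test_that("DFA variance slope matches a second implementation and references", {
  scales <- c(4, 8, 16, 32, 64)
  expect_true(is.na(dfa_variance_slope(rep(800, 200), scales)))

  # equals the textbook fluctuation-convention DFA with slope doubled
  set.seed(12)
  x <- rnorm(400, 800, 30)
  expect_equal(dfa_variance_slope(x, scales),
               2 * oracle_dfa_alpha(x, scales), tolerance = 1e-8)
  # the log-F convention halves the statistic exactly
  expect_equal(dfa_variance_slope(x, scales, use_log_f2 = FALSE),
               oracle_dfa_alpha(x, scales), tolerance = 1e-8)

  # white-noise reference: mean slope near 1.0 (modest MC here)
  set.seed(21)
  slopes <- replicate(30, dfa_variance_slope(rnorm(1000), scales))
  expect_lt(abs(mean(slopes) - 1), 0.1)

  # integrated noise is strongly trending: slope well above 1.5
  set.seed(22)
  trending <- replicate(10, dfa_variance_slope(cumsum(rnorm(1000)), scales))
  expect_gt(mean(trending), 1.5)
})

test_that("SDNN is the sample SD with a minimum-beat guard", {
  expect_equal(as.numeric(sdnn(rep(1000, 50))), 0)
  expect_equal(as.numeric(sdnn(c(900, 1100))), 200 / sqrt(2),
               tolerance = 1e-10)
  expect_true(is.na(sdnn(c(900, 1100), min_beats = 100)))
  set.seed(3)
  expect_lt(abs(as.numeric(sdnn(rnorm(4000, 800, 50))) - 50), 2)
})

test_that("median imputation fills gaps and preserves flags", {
  co <- generate_cohort(quick_config(n = 4, seed = 2, event_fraction = 0.5))
  feats <- cohort_features(co, feature_params())
  med <- feature_medians(feats)

  # medians agree with an independent order-statistic computation
  for (nm in c("hr_mean", "cosen", "dfa_slope")) {
    x <- sort(feats[[nm]][!is.na(feats[[nm]])])
    n <- length(x)
    m_oracle <- if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
    expect_equal(unname(med[nm]), m_oracle)
  }

  imp <- impute_missing(feats, med)
  expect_false(anyNA(imp[feature_names()]))
  # no-missing rows unchanged
  full <- !apply(is.na(feats[feature_names()]), 1, any)
  expect_equal(imp[full, feature_names()], feats[full, feature_names()])
  # flags mark exactly the filled cells
  expect_identical(imp$cosen_imputed, is.na(feats$cosen))
  # an all-missing row becomes the medians row exactly
  feats2 <- feats
  feats2[1, feature_names()] <- NA_real_
  imp2 <- impute_missing(feats2, med)
  expect_equal(unlist(imp2[1, feature_names()]), med)

  expect_error(impute_missing(feats, c(med, bogus = 1)), "unknown feature")
  expect_error(impute_missing(feats, med[-1]), "missing for feature")
})
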