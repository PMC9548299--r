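risk_tbl <- function(id, ends, rr) {
  tibble::tibble(admission_id = id, window_end_min = ends, relative_risk = rr)
}

adm_tbl <- function(ids, events) {
  tibble::tibble(admission_id = ids, event_time_min = events)
}

test_that("risk series align on the 15-min pre-event grid", {
  risk <- risk_tbl("A", c(4785, 4800), c(2.0, 3.0))
  adm <- adm_tbl(c("A", "B"), c(4800, NA))
  m <- align_to_event(risk, adm, max_hours = 2)
  expect_identical(dim(m), c(1L, 9L))
  expect_equal(m["A", "-15"], 2.0)
  expect_equal(m["A", "0"], 3.0)
  expect_true(all(is.na(m["A", as.character(seq(-120, -30, 15))])))

  # admissions monitored only far from the event populate leading columns only
  risk2 <- risk_tbl("A", seq(15, 600, 15), rep(1, 40))
  adm2 <- adm_tbl("A", 2400)
  m2 <- align_to_event(risk2, adm2, max_hours = 48)
  pop <- colnames(m2)[!is.na(m2[1, ])]
  expect_true(all(as.numeric(pop) <= 600 - 2400))

  # risk rows from event-less admissions are dropped with a message
  expect_message(align_to_event(risk_tbl("C", 100, 1), adm, max_hours = 2),
                 "without event")
})

test_that("trajectory means carry SEM confidence ribbons", {
  m <- matrix(c(1, 2, 1, 2), nrow = 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c(-15, 0)))
  tr <- mean_trajectory_ci(m)
  expect_equal(tr$mean, c(1, 2))
  expect_equal(tr$ci_low, tr$ci_high)  # identical rows: zero-width ribbon

  m1 <- matrix(c(1.5, 2.5), nrow = 1, dimnames = list("A", c(-15, 0)))
  tr1 <- mean_trajectory_ci(m1)
  expect_equal(tr1$n, c(1L, 1L))
  expect_true(all(is.na(tr1$ci_low)))  # CI undefined at n = 1

  # offsets with no data are omitted
  m2 <- matrix(c(NA, 3), nrow = 1, dimnames = list("A", c(-15, 0)))
  expect_equal(mean_trajectory_ci(m2)$offset_min, 0)
})

test_that("signed-rank lag test: exact branch, enumeration oracle, ties", {
  # n = 6 all-positive differences: p = 2^-6
  res <- signed_rank_greater(rep(1.5, 6) + (1:6) / 100)
  expect_equal(res$p_value, 1 / 64)

  # exact DP equals full 2^n enumeration on random paired differences
  set.seed(41)
  for (i in 1:12) {
    d <- round(rnorm(sample(5:12, 1)), 2)  # rounding induces ties
    d <- d[d != 0]
    if (length(d) < 2) next
    expect_equal(signed_rank_greater(d)$p_value, oracle_signed_rank_p(d),
                 tolerance = 1e-12)
  }

  # no ties: agrees with the base exact signed-rank test
  set.seed(42)
  d <- rnorm(15)
  expect_equal(signed_rank_greater(d)$p_value,
               stats::wilcox.test(d, alternative = "greater",
                                  exact = TRUE)$p.value,
               tolerance = 1e-12)
  # large-sample branch matches the normal approximation with correction
  d <- rnorm(40)
  expect_equal(signed_rank_greater(d, exact_max = 25)$p_value,
               suppressWarnings(
                 stats::wilcox.test(d, alternative = "greater",
                                    exact = FALSE, correct = TRUE)$p.value
               ),
               tolerance = 1e-10)

  # all-zero differences at some offset: untested
  m <- matrix(rep(1, 2 * 97), nrow = 2,
              dimnames = list(c("A", "B"), seq(-24 * 60, 0, 15)))
  out <- signed_rank_lag_test(m, lag_hours = 12)
  expect_true(all(is.na(out$p_value)))
  expect_true(all(out$n_pairs == 0))
})

test_that("AUC is the tie-aware concordance probability", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(4, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")

  set.seed(77)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    s <- sample(round(rnorm(n), 1))  # ties likely
    l <- rbinom(n, 1, 0.4)
    if (length(unique(l)) < 2) next
    expect_equal(roc_auc(s, l), oracle_auc(s, l))
  }
})

test_that("window-dependent AUC uses nested labels and a seeded bootstrap", {
  set.seed(8)
  ids <- sprintf("P%02d", 1:30)
  events <- ifelse(seq_along(ids) <= 10, 48 * 60, NA)
  risk <- do.call(rbind, lapply(seq_along(ids), function(i) {
    ends <- seq(15 * 60, 48 * 60, 15)
    tau <- ifelse(is.na(events[i]), Inf, events[i] - ends)
    rr <- exp(rnorm(length(ends), ifelse(tau < 6 * 60, 1, 0), 0.3))
    risk_tbl(ids[i], ends, rr)
  }))
  adm <- adm_tbl(ids, events)

  curve <- auc_vs_window(risk, adm, windows_hours = c(4, 12, 24),
                         n_boot = 30, seed = 5)
  expect_true(all(curve$auc >= 0 & curve$auc <= 1))
  expect_true(all(curve$ci_low <= curve$auc & curve$auc <= curve$ci_high))
  # nesting: wider windows can only add positives
  expect_true(all(diff(curve$n_event_epochs) > 0))
  # determinism under the seeded resampler
  curve2 <- auc_vs_window(risk, adm, windows_hours = c(4, 12, 24),
                          n_boot = 30, seed = 5)
  expect_identical(curve, curve2)
})

test_that("decile calibration partitions measurements and conserves risk", {
  set.seed(10)
  n <- 400
  ids <- sprintf("M%03d", 1:n)
  y <- rbinom(n, 1, 0.2)
  adm <- adm_tbl(ids, ifelse(y == 1, 60, NA))  # event 1 h after the epoch
  risk <- risk_tbl(ids, rep(0, n), exp(rnorm(n)))
  train_mean_p <- 0.2

  cal <- calibration_deciles(risk, adm, train_mean_p, horizon_hours = 12)
  expect_identical(nrow(cal), 10L)
  expect_equal(sum(cal$n), n)
  expect_true(all(abs(cal$n - n / 10) <= 1))
  # conservation: decile-weighted observed risk equals the overall rate
  expect_equal(sum(cal$observed_rr * cal$n) / n, mean(y) / train_mean_p,
               tolerance = 1e-12)

  # constant predictions: tie group split into equal deciles, equal x
  risk_c <- risk_tbl(ids, rep(0, n), rep(2, n))
  cal_c <- calibration_deciles(risk_c, adm, train_mean_p)
  expect_true(all(cal_c$mean_predicted_rr == 2))
  expect_true(all(cal_c$n == n / 10))
  # stable tie order is reproducible
  expect_identical(cal_c, calibration_deciles(risk_c, adm, train_mean_p))

  # a decile with no pre-event measurements observes zero risk
  risk_s <- risk_tbl(ids, rep(0, n), rank(-y) + runif(n) / 10)
  cal_s <- calibration_deciles(risk_s, adm, train_mean_p)
  expect_equal(cal_s$observed_rr[10], 0)

  expect_error(calibration_deciles(risk[1:5, ], adm, 0.2), "at least 10")
})
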