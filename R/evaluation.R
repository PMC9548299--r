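#' Align relative-risk series to the event time
#'
#' Every-15-min risk estimates of event admissions are aligned relative to
#' the time of emergent intubation (time zero). Cell `(i, tau)` holds
#' admission `i`'s relative risk at `event_time + tau` for `tau <= 0`,
#' snapped to the nearest 15-min grid offset; cells are `NA` where the
#' admission was censored or unmonitored. Admissions without an event are
#' excluded (with a message).
#'
#' @param risk Tibble `admission_id`, `window_end_min`, `relative_risk`
#'   (uncensored epochs only).
#' @param admissions Tibble `admission_id`, `event_time_min`.
#' @param max_hours Span of the pre-event axis (default 48 h).
#' @return Numeric matrix, rows = event admissions, columns = offsets
#'   `seq(-max_hours * 60, 0, by = 15)` (dimnames carry ids and offsets).
#' @export
align_to_event <- function(risk, admissions, max_hours = 48) {
  ev <- admissions[!is.na(admissions$event_time_min), , drop = FALSE]
  dropped <- setdiff(unique(risk$admission_id), ev$admission_id)
  if (length(dropped)) {
    message(length(dropped), " admission(s) without event excluded from alignment")
  }
  offsets <- seq(-max_hours * 60, 0, by = 15)
  mat <- matrix(NA_real_, nrow = nrow(ev), ncol = length(offsets),
                dimnames = list(ev$admission_id, offsets))
  for (i in seq_len(nrow(ev))) {
    rs <- risk[risk$admission_id == ev$admission_id[i], , drop = FALSE]
    if (!nrow(rs)) next
    tau <- rs$window_end_min - ev$event_time_min[i]
    snap <- round(tau / 15) * 15
    ok <- snap <= 0 & snap >= -max_hours * 60
    if (!any(ok)) next
    col <- match(snap[ok], offsets)
    mat[i, col] <- rs$relative_risk[ok]
  }
  mat
}

#' Mean event-aligned trajectory with 95% confidence ribbon
#'
#' Per 15-min offset: the mean relative risk over admissions with data and
#' the normal-approximation 95% CI, `mean +/- 1.96 * SD / sqrt(n)`. Offsets
#' with no data are omitted; `n = 1` offsets report an absent CI.
#'
#' @param aligned Matrix from [align_to_event()].
#' @return Tibble `offset_min`, `n`, `mean`, `ci_low`, `ci_high`.
#' @export
mean_trajectory_ci <- function(aligned) {
  empty <- tibble::tibble(offset_min = numeric(), n = integer(),
                          mean = numeric(), ci_low = numeric(),
                          ci_high = numeric())
  if (nrow(aligned) == 0) return(empty)
  offsets <- as.numeric(colnames(aligned))
  rows <- lapply(seq_along(offsets), function(j) {
    x <- aligned[, j]
    x <- x[!is.na(x)]
    n <- length(x)
    if (n == 0) return(NULL)
    m <- mean(x)
    if (n == 1) {
      ci <- c(NA_real_, NA_real_)
    } else {
      half <- 1.96 * sd(x) / sqrt(n)
      ci <- c(m - half, m + half)
    }
    tibble::tibble(offset_min = offsets[j], n = n, mean = m,
                   ci_low = ci[1], ci_high = ci[2])
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Paired signed-rank test against the risk 12 h earlier
#'
#' At each 15-min offset, a one-sided (greater) Wilcoxon signed-rank test
#' of the null that risk equals the same admission's risk `lag_hours`
#' earlier. Zero differences are dropped (Wilcoxon convention). The exact
#' null distribution (midrank dynamic programming over sign flips) is used
#' for up to `exact_max` pairs; beyond that, the normal approximation with
#' tie correction and continuity correction. Offsets with fewer than
#' `min_pairs` non-zero pairs are reported untested (`NA` p).
#'
#' @param aligned Matrix from [align_to_event()].
#' @param lag_hours Comparison lag (default 12 h).
#' @param min_pairs Minimum non-zero pairs to test (default 5).
#' @param exact_max Largest n for the exact branch (default 25).
#' @return Tibble `offset_min`, `n_pairs`, `statistic` (rank sum of
#'   positive differences), `p_value`.
#' @export
signed_rank_lag_test <- function(aligned, lag_hours = 12, min_pairs = 5,
                                 exact_max = 25) {
  offsets <- as.numeric(colnames(aligned))
  lag_min <- lag_hours * 60
  rows <- lapply(seq_along(offsets), function(j) {
    j0 <- match(offsets[j] - lag_min, offsets)
    if (is.na(j0)) return(NULL)
    d <- aligned[, j] - aligned[, j0]
    d <- d[!is.na(d)]
    d <- d[d != 0]
    n <- length(d)
    if (n < min_pairs) {
      return(tibble::tibble(offset_min = offsets[j], n_pairs = n,
                            statistic = NA_real_, p_value = NA_real_))
    }
    res <- signed_rank_greater(d, exact_max)
    tibble::tibble(offset_min = offsets[j], n_pairs = n,
                   statistic = res$statistic, p_value = res$p_value)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(tibble::tibble(offset_min = numeric(), n_pairs = integer(),
                          statistic = numeric(), p_value = numeric()))
  }
  do.call(rbind, rows)
}

#' One-sided signed-rank p-value for nonzero paired differences
#'
#' @param d Nonzero paired differences.
#' @param exact_max Largest n handled by the exact branch.
#' @return List with `statistic` (W+, rank sum of positive differences)
#'   and one-sided (greater) `p_value`.
#' @export
signed_rank_greater <- function(d, exact_max = 25) {
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_max) {
    # exact null: signs flip independently; DP over doubled midranks
    r2 <- as.integer(round(2 * r))
    f <- numeric(sum(r2) + 1)
    f[1] <- 1
    for (rk in r2) {
      shifted <- c(numeric(rk), f[seq_len(length(f) - rk)])
      f <- f + shifted
    }
    W2 <- as.integer(round(2 * W))
    p <- sum(f[(W2 + 1):length(f)]) / 2^n
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - 0.5) / sqrt(sig2)  # continuity correction
    p <- pnorm(z, lower.tail = FALSE)
  }
  list(statistic = W, p_value = p)
}

#' Area under the ROC curve (C-statistic)
#'
#' Mann-Whitney form: the probability that a randomly chosen event epoch
#' outscores a randomly chosen control epoch, ties counted 1/2.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("both classes must be present to compute AUC", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUC as a function of the event-window size, with admission bootstrap
#'
#' For each detection window `w` (hours), epochs of event admissions
#' ending within `(0, w]` hours before the event are positives; all other
#' uncensored epochs (controls, and event admissions far from the event)
#' are negatives. 95% CIs are percentile intervals over bootstrap
#' resamples drawn by hospital admission with replacement (all epochs of a
#' sampled admission enter together); single-class replicates are redrawn
#' and counted.
#'
#' @param risk Tibble `admission_id`, `window_end_min`, `relative_risk`.
#' @param admissions Tibble `admission_id`, `event_time_min` (`NA` for
#'   controls).
#' @param windows_hours Detection windows (default `seq(4, 24, by = 2)`).
#' @param n_boot Bootstrap replicates (default 200).
#' @param seed Integer seed for the resampler.
#' @return Tibble `window_hours`, `auc`, `ci_low`, `ci_high`,
#'   `n_event_epochs`, `n_redrawn`.
#' @export
auc_vs_window <- function(risk, admissions, windows_hours = seq(4, 24, 2),
                          n_boot = 200, seed = 1L) {
  ev_time <- stats::setNames(admissions$event_time_min,
                             admissions$admission_id)
  tau <- ev_time[risk$admission_id] - risk$window_end_min  # NA for controls
  ids <- unique(risk$admission_id)
  rows_of <- split(seq_len(nrow(risk)), risk$admission_id)

  label_for <- function(w) {
    as.integer(!is.na(tau) & tau > 0 & tau <= w * 60)
  }

  out <- lapply(windows_hours, function(w) {
    lab <- label_for(w)
    auc <- roc_auc(risk$relative_risk, lab)
    n_redrawn <- 0L
    boot <- withr::with_seed(seed + as.integer(w), {
      vapply(seq_len(n_boot), function(b) {
        repeat {
          take <- sample(ids, length(ids), replace = TRUE)
          idx <- unlist(rows_of[take], use.names = FALSE)
          lb <- lab[idx]
          if (any(lb == 1) && any(lb == 0)) {
            return(roc_auc(risk$relative_risk[idx], lb))
          }
          n_redrawn <<- n_redrawn + 1L
          if (n_redrawn > 100 * n_boot) return(NA_real_)
        }
      }, numeric(1))
    })
    ci <- quantile(boot, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    tibble::tibble(window_hours = w, auc = auc, ci_low = ci[1],
                   ci_high = ci[2], n_event_epochs = sum(lab),
                   n_redrawn = n_redrawn)
  })
  do.call(rbind, out)
}

#' Decile calibration of predicted relative risk
#'
#' Uncensored measurements are ranked by predicted relative risk (stable
#' order: predicted value, admission, time) and cut into 10 equal-count
#' groups. Per decile: x = mean predicted relative risk; y = observed
#' relative risk, i.e. the proportion of measurements within
#' `horizon_hours` of an emergent intubation divided by the development
#' mean event probability. Perfect calibration lies on the identity line.
#'
#' @param risk Tibble `admission_id`, `window_end_min`, `relative_risk`.
#' @param admissions Tibble `admission_id`, `event_time_min`.
#' @param train_mean_p Development-set mean predicted event probability.
#' @param horizon_hours Observation window (default 12 h).
#' @return Tibble with 10 rows: `decile`, `n`, `mean_predicted_rr`,
#'   `observed_rr`.
#' @export
calibration_deciles <- function(risk, admissions, train_mean_p,
                                horizon_hours = 12) {
  n <- nrow(risk)
  if (n < 10) stop("need at least 10 uncensored measurements", call. = FALSE)
  ev_time <- stats::setNames(admissions$event_time_min,
                             admissions$admission_id)
  tau <- ev_time[risk$admission_id] - risk$window_end_min
  observed <- as.integer(!is.na(tau) & tau > 0 & tau <= horizon_hours * 60)
  ord <- order(risk$relative_risk, risk$admission_id, risk$window_end_min,
               method = "radix")
  decile <- integer(n)
  decile[ord] <- ceiling(seq_len(n) * 10 / n)
  out <- lapply(1:10, function(d) {
    sel <- decile == d
    tibble::tibble(decile = d, n = sum(sel),
                   mean_predicted_rr = mean(risk$relative_risk[sel]),
                   observed_rr = mean(observed[sel]) / train_mean_p)
  })
  do.call(rbind, out)
}

#' Patient-years of monitored risk estimates
#'
#' Converts a count of fixed-width monitoring epochs into patient-years
#' (365.25 days/year), the scale on which study-wide monitoring volume is
#' reported.
#'
#' @param n_epochs Number of epochs.
#' @param epoch_minutes Epoch width in minutes (default 15).
#' @return Patient-years.
#' @export
monitored_patient_years <- function(n_epochs, epoch_minutes = 15) {
  n_epochs * epoch_minutes / 60 / 24 / 365.25
}
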