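#' Parameters of the windowed feature extraction
#'
#' Predictors are computed in 30-minute windows advanced every 15 minutes
#' (50% overlap) and stamped at the window end, yielding an every-15-min
#' feature grid.
#'
#' @param window_width Window width in minutes (default 30).
#' @param step Grid step in minutes (default `window_width / 2`).
#' @param sampen_m Sample-entropy template length (default 1).
#' @param sampen_r Sample-entropy tolerance in ms (default 30).
#' @param dfa_scales Increasing box sizes in beats for detrended
#'   fluctuation analysis (default 4, 8, 16, 32, 64; each >= 4).
#' @param min_samples_per_window Minimum non-missing vitals samples for a
#'   windowed statistic (default 10).
#' @param min_beats_per_window Minimum beats for RR-interval measures
#'   (default 100).
#' @param dfa_log_f2 If `TRUE` (default) the DFA regression uses
#'   `log F^2(n)` (variance), so iid noise has reference slope 1.0; if
#'   `FALSE` it uses `log F(n)` (fluctuation, reference slope 0.5).
#' @return List of class `"feature_params"`.
#' @export
feature_params <- function(window_width = 30, step = window_width / 2,
                           sampen_m = 1, sampen_r = 30,
                           dfa_scales = c(4, 8, 16, 32, 64),
                           min_samples_per_window = 10,
                           min_beats_per_window = 100,
                           dfa_log_f2 = TRUE) {
  stopifnot(window_width > 0, step > 0, sampen_m >= 1, sampen_r > 0,
            all(diff(dfa_scales) > 0), all(dfa_scales >= 4))
  structure(list(window_width = window_width, step = step,
                 sampen_m = sampen_m, sampen_r = sampen_r,
                 dfa_scales = dfa_scales,
                 min_samples_per_window = min_samples_per_window,
                 min_beats_per_window = min_beats_per_window,
                 dfa_log_f2 = dfa_log_f2),
            class = "feature_params")
}

#' Feature windows over a time span
#'
#' Windows are `[e - window_width, e]` for ends
#' `e = t_start + window_width, t_start + window_width + step, ... <= t_end`.
#'
#' @param t_start,t_end Span in minutes, `t_end > t_start`.
#' @param params A [feature_params()].
#' @return Tibble with `start_min`, `end_min`; zero rows when the span is
#'   shorter than the window width.
#' @export
iter_windows <- function(t_start, t_end, params = feature_params()) {
  if (t_end <= t_start) stop("t_end must exceed t_start", call. = FALSE)
  if (t_end - t_start < params$window_width) {
    return(tibble::tibble(start_min = numeric(), end_min = numeric()))
  }
  ends <- seq(t_start + params$window_width, t_end, by = params$step)
  tibble::tibble(start_min = ends - params$window_width, end_min = ends)
}

# Samples in the half-open window (start, end]; windows then tile the
# per-minute grid without double-counting boundary samples.
window_slice <- function(t, start, end) which(t > start & t <= end)

#' Windowed vital-sign means and standard deviations
#'
#' @param vitals Tibble from [simulate_vitals()] (columns `t_min`, `hr`,
#'   `rr`, `spo2`, `sbp`; may contain `NA`).
#' @param window Numeric `c(start, end)` in minutes.
#' @param params A [feature_params()].
#' @return Named numeric vector `hr_mean, hr_sd, ..., sbp_sd`; sample SD
#'   (denominator n-1) over non-missing samples; `NA` when fewer than
#'   `min_samples_per_window` samples are present.
#' @export
window_vitals_stats <- function(vitals, window, params = feature_params()) {
  idx <- window_slice(vitals$t_min, window[1], window[2])
  out <- numeric(0)
  for (ch in channel_names()) {
    x <- vitals[[ch]][idx]
    x <- x[!is.na(x)]
    if (length(x) < params$min_samples_per_window) {
      m <- s <- NA_real_
    } else {
      m <- mean(x); s <- sd(x)
    }
    out[paste0(ch, "_mean")] <- m
    out[paste0(ch, "_sd")] <- s
  }
  out
}

channel_pairs <- function() {
  chs <- channel_names()
  pairs <- utils::combn(chs, 2)
  lapply(seq_len(ncol(pairs)), function(i) pairs[, i])
}

#' Windowed zero-lag cross-correlations between vital signs
#'
#' Pearson correlation at lag zero on the common per-minute grid, over
#' pairwise-complete samples; `NA` when the overlap is below
#' `min_samples_per_window` or either channel is constant.
#'
#' @inheritParams window_vitals_stats
#' @return Named numeric vector `cc_hr_rr, ..., cc_spo2_sbp`, each in
#'   `[-1, 1]` or `NA`.
#' @export
window_cross_correlations <- function(vitals, window,
                                      params = feature_params()) {
  idx <- window_slice(vitals$t_min, window[1], window[2])
  out <- numeric(0)
  for (pr in channel_pairs()) {
    x <- vitals[[pr[1]]][idx]; y <- vitals[[pr[2]]][idx]
    ok <- !is.na(x) & !is.na(y)
    nm <- paste0("cc_", pr[1], "_", pr[2])
    if (sum(ok) < params$min_samples_per_window ||
        sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      out[nm] <- NA_real_
    } else {
      out[nm] <- stats::cor(x[ok], y[ok])
    }
  }
  out
}

#' Sample entropy of an RR-interval series
#'
#' `SampEn = -ln(A/B)` with Chebyshev distance and self-matches excluded:
#' `B` counts matching pairs among all `n - m + 1` templates of length `m`,
#' `A` among the `n - m` templates of length `m + 1`, both within
#' tolerance `r`.
#'
#' @param intervals Numeric RR intervals, ms.
#' @param m Template length (>= 1).
#' @param r Tolerance, ms (> 0).
#' @return SampEn in nats; `NA` (with a `"reason"` attribute) when the
#'   series is shorter than `m + 2` or no template pair matches.
#' @export
sample_entropy <- function(intervals, m = 1, r = 30) {
  intervals <- intervals[!is.na(intervals)]
  if (length(intervals) < m + 2) {
    return(structure(NA_real_, reason = "too few beats"))
  }
  counts <- sampen_counts_cpp(as.numeric(intervals), as.integer(m),
                              as.numeric(r))
  if (anyNA(counts) || counts[1] == 0 || counts[2] == 0) {
    return(structure(NA_real_, reason = "no template matches"))
  }
  -log(counts[2] / counts[1])
}

#' Coefficient of sample entropy (COSEn)
#'
#' `COSEn = SampEn(m, r) + ln(2 r) - ln(mean RR)`, with `r` and the mean
#' RR interval in ms. The correction terms make the entropy rate robust to
#' record length and heart rate, as used for RR-interval dynamics.
#'
#' @inheritParams sample_entropy
#' @return COSEn in nats, or `NA` when SampEn is undefined.
#' @export
cosen <- function(intervals, m = 1, r = 30) {
  intervals <- intervals[!is.na(intervals)]
  mu <- mean(intervals)
  if (!is.finite(mu) || mu <= 0) {
    return(structure(NA_real_, reason = "nonpositive mean RR"))
  }
  se <- sample_entropy(intervals, m, r)
  if (is.na(se)) return(se)
  se + log(2 * r) - log(mu)
}

#' DFA variance slope of an RR-interval series
#'
#' Detrended fluctuation analysis: the mean-subtracted intervals are
#' integrated, partitioned into non-overlapping boxes of `n` beats (the
#' partition taken from both ends and averaged), linearly detrended per
#' box, and the mean squared residual `F^2(n)` computed. The returned
#' statistic is the least-squares slope of `log F^2(n)` against `log n`
#' over `dfa_scales` (so iid intervals give slope ~1.0, i.e. twice the
#' conventional scaling exponent alpha ~0.5); set `use_log_f2 = FALSE`
#' for the `log F(n)` convention.
#'
#' @param intervals Numeric RR intervals, ms.
#' @param dfa_scales Increasing box sizes in beats.
#' @param use_log_f2 Regress `log F^2` (default) or `log F`.
#' @return Slope (unitless); `NA` (with reason) when fewer than
#'   `2 * max(dfa_scales)` beats are available or any `F(n)` is zero.
#' @export
dfa_variance_slope <- function(intervals, dfa_scales = c(4, 8, 16, 32, 64),
                               use_log_f2 = TRUE) {
  x <- intervals[!is.na(intervals)]
  n_beats <- length(x)
  if (n_beats < 2 * max(dfa_scales)) {
    return(structure(NA_real_, reason = "too few beats"))
  }
  y <- cumsum(x - mean(x))
  f2 <- vapply(dfa_scales, function(n) {
    nb <- floor(n_beats / n)
    fwd <- box_msr(y[seq_len(nb * n)], n)
    bwd <- box_msr(y[seq.int(n_beats - nb * n + 1, n_beats)], n)
    mean(c(fwd, bwd))
  }, numeric(1))
  if (any(f2 <= 0)) {
    return(structure(NA_real_, reason = "zero fluctuation"))
  }
  resp <- if (use_log_f2) log(f2) else log(sqrt(f2))
  unname(coef(lm(resp ~ log(dfa_scales)))[2])
}

# Mean squared residual of per-box linear detrending; y reshaped into
# boxes of n points, closed-form simple regression per box.
box_msr <- function(y, n) {
  nb <- length(y) / n
  Y <- matrix(y, nrow = n)
  t <- seq_len(n)
  st <- sum(t); stt_c <- sum(t^2) - st^2 / n
  sy <- colSums(Y)
  sty_c <- colSums(t * Y) - st * sy / n
  syy_c <- colSums(Y^2) - sy^2 / n
  beta <- sty_c / stt_c
  msr <- (syy_c - beta^2 * stt_c) / n
  pmax(msr, 0)  # guard tiny negative round-off
}

#' SDNN of a window of RR intervals
#'
#' Sample standard deviation (denominator n-1) of the intervals.
#'
#' @param intervals Numeric RR intervals, ms.
#' @param min_beats Minimum beats required (default 2 here; callers pass
#'   `min_beats_per_window`).
#' @return SDNN in ms, or `NA` when too few beats.
#' @export
sdnn <- function(intervals, min_beats = 2) {
  x <- intervals[!is.na(intervals)]
  if (length(x) < max(2, min_beats)) {
    return(structure(NA_real_, reason = "too few beats"))
  }
  sd(x)
}

#' Names of all computed features
#' @return Character vector of the 17 feature column names.
#' @export
feature_names <- function() {
  c(paste0(rep(channel_names(), each = 2), c("_mean", "_sd")),
    vapply(channel_pairs(), function(p) paste0("cc_", p[1], "_", p[2]),
           character(1)),
    "sdnn", "cosen", "dfa_slope")
}

#' Compute the full feature set for one admission
#'
#' Walks the every-15-min window grid over the stay, drops censored
#' windows, and computes windowed vital-sign statistics,
#' cross-correlations, SDNN, COSEn and the DFA variance slope.
#'
#' @param record An `"admission_record"` (or a list with `admission_id`,
#'   `duration_min`, `vitals`, `rr_intervals`).
#' @param params A [feature_params()].
#' @param vent_epochs Optional reconstructed ventilation epochs used for
#'   censoring (with [censor_mask()]); windows whose end falls in a
#'   ventilated epoch, or any window of a DNI admission, produce no row.
#' @return Tibble: `admission_id`, `window_end_min`, one column per
#'   feature (see [feature_names()]); missing features are `NA`.
#' @export
compute_features <- function(record, params = feature_params(),
                             vent_epochs = NULL) {
  win <- iter_windows(0, record$duration_min, params)
  if (nrow(win) == 0) return(empty_features())
  keep <- !censor_mask(win$end_min, vent_epochs, dni = isTRUE(record$dni))
  win <- win[keep, , drop = FALSE]
  if (nrow(win) == 0) return(empty_features())

  bt <- record$rr_intervals$beat_time_min
  rr <- record$rr_intervals$rr_ms
  # beat times are sorted: locate each window's beats by binary search
  lo <- findInterval(win$start_min, bt) + 1     # first beat with t > start
  hi <- findInterval(win$end_min, bt)           # last beat with t <= end
  rows <- lapply(seq_len(nrow(win)), function(i) {
    w <- c(win$start_min[i], win$end_min[i])
    stats_v <- window_vitals_stats(record$vitals, w, params)
    ccs <- window_cross_correlations(record$vitals, w, params)
    iv <- if (hi[i] >= lo[i]) rr[lo[i]:hi[i]] else numeric(0)
    iv <- iv[!is.na(iv)]
    enough <- length(iv) >= params$min_beats_per_window
    c(stats_v, ccs,
      sdnn = if (enough) as.numeric(sdnn(iv)) else NA_real_,
      cosen = if (enough) {
        as.numeric(cosen(iv, params$sampen_m, params$sampen_r))
      } else NA_real_,
      dfa_slope = if (enough && length(iv) >= 2 * max(params$dfa_scales)) {
        as.numeric(dfa_variance_slope(iv, params$dfa_scales,
                                      params$dfa_log_f2))
      } else NA_real_)
  })
  mat <- do.call(rbind, rows)
  out <- tibble::as_tibble(as.data.frame(mat))
  names(out) <- feature_names()
  tibble::add_column(out, admission_id = record$admission_id,
                     window_end_min = win$end_min, .before = 1)
}

empty_features <- function() {
  out <- tibble::as_tibble(
    stats::setNames(rep(list(numeric()), length(feature_names())),
                    feature_names())
  )
  tibble::add_column(out, admission_id = character(),
                     window_end_min = numeric(), .before = 1)
}

#' Compute features for a whole cohort
#'
#' @param cohort An `"icu_cohort"`.
#' @param params A [feature_params()].
#' @param rules An [epoch_rules()]; ventilation epochs are reconstructed
#'   from each admission's flowsheet and reconciled with its event times
#'   before censoring.
#' @return Tibble of stacked per-admission feature rows.
#' @export
cohort_features <- function(cohort, params = feature_params(),
                            rules = epoch_rules()) {
  res <- lapply(cohort, function(rec) {
    ep <- build_epochs(rec$flowsheet, rules)
    ep <- split_at_intubation(ep, rec$flowsheet, rec$event_times_min,
                              rules, admission_end = rec$duration_min)
    compute_features(rec, params, vent_epochs = ep)
  })
  do.call(rbind, res)
}

#' Per-feature medians of a development feature table
#'
#' @param features Feature tibble from [cohort_features()].
#' @return Named numeric vector of medians over non-missing values.
#' @export
feature_medians <- function(features) {
  vapply(feature_names(), function(nm) {
    median(features[[nm]], na.rm = TRUE)
  }, numeric(1))
}

#' Impute missing features with reference medians
#'
#' Missing (`NA`) feature values are replaced by reference medians —
#' computed from the development split, standing in for the original
#' development-cohort medians. One `<feature>_imputed` flag column per
#' feature records which entries were filled.
#'
#' @param features Feature tibble.
#' @param medians Named numeric vector covering every feature column.
#' @return The feature tibble with `NA`s replaced and `*_imputed` flags
#'   appended.
#' @export
impute_missing <- function(features, medians) {
  unknown <- setdiff(names(medians), feature_names())
  if (length(unknown)) {
    stop("unknown feature name in medians table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  absent <- setdiff(feature_names(), names(medians))
  if (length(absent)) {
    stop("medians missing for feature: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  for (nm in feature_names()) {
    miss <- is.na(features[[nm]])
    features[[paste0(nm, "_imputed")]] <- miss
    features[[nm]][miss] <- medians[[nm]]
  }
  features
}
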