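#' Configuration for a synthetic ICU cohort
#'
#' Bundles and validates every parameter of the synthetic cohort generator.
#' The defaults describe the world the downstream analyses assume: control
#' admissions with stationary AR(1) vital signs, event admissions with a
#' smooth multi-hour deterioration before emergent intubation (rising heart
#' and respiratory rate, falling SpO2 and blood pressure, shrinking
#' RR-interval variability), sparse respiratory-therapist flowsheet
#' documentation during mechanical ventilation, and a small fraction of
#' DNI admissions to exclude.
#'
#' @param n_admissions Number of ICU admissions to simulate.
#' @param event_fraction Fraction of admissions experiencing respiratory
#'   failure leading to emergent intubation. `round(n * event_fraction)`
#'   admissions get an event.
#' @param dni_fraction Fraction of admissions under Do-Not-Intubate orders
#'   (generated as controls, censored entirely downstream).
#' @param stay_meanlog,stay_sdlog Lognormal parameters of the ICU stay
#'   duration in hours (default: median 48 h).
#' @param min_stay_hours Floor on stay duration; event admissions are
#'   additionally floored at 26 h so an event time can be drawn in
#'   `[24 h, duration]`.
#' @param ramp_hours Duration of the linear pre-event deterioration ramp.
#' @param effect_sizes Named numeric vector `c(hr=, rr=, spo2=, sbp=)`:
#'   per-channel mean shift reached at the event time (bpm, breaths/min,
#'   %SpO2, mmHg).
#' @param rr_variability_shrink Multiplicative factor in (0, 1] applied to
#'   the RR-interval SD at the event time (1 = no shrink).
#' @param ar_coefficient AR(1) persistence of the per-minute vital-sign
#'   noise, in `[0, 1)`.
#' @param noise_sd Named numeric vector of stationary noise SDs per channel.
#' @param baseline Named numeric vector of baseline channel levels.
#' @param between_sd Named numeric vector of between-admission SDs of the
#'   baseline levels: each admission draws its own resting level (real ICU
#'   populations are heterogeneous; without this, any mean shift would be
#'   perfectly discriminable).
#' @param mean_rr,sd_rr Mean and SD of RR intervals in ms.
#' @param mean_rr_between_sd Between-admission SD of the mean RR interval,
#'   ms.
#' @param effect_scale_sd Lognormal SD of a per-admission multiplier on
#'   the deterioration effect sizes (median multiplier 1; 0 = identical
#'   deterioration in every event admission).
#' @param doc_interval Length-2 numeric: range (hours) of gaps between
#'   consecutive ventilator respiratory-rate flowsheet entries.
#' @param missing_rate Per-channel random dropout probability for vital
#'   signs, to exercise median imputation.
#' @param control_vent_fraction Fraction of control admissions given a
#'   ventilation epoch unrelated to any event (default 0: controls are
#'   never ventilated).
#' @param allow_multi_event If `TRUE`, a small fraction of event admissions
#'   receive a second emergent intubation after extubation.
#' @param seed Integer seed; a fixed seed yields a byte-identical cohort.
#'
#' @return A validated list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_admissions = 200,
                          event_fraction = 0.25,
                          dni_fraction = 0.05,
                          stay_meanlog = log(48),
                          stay_sdlog = 0.35,
                          min_stay_hours = 6,
                          ramp_hours = 12,
                          effect_sizes = c(hr = 25, rr = 12, spo2 = -8, sbp = -15),
                          rr_variability_shrink = 0.5,
                          ar_coefficient = 0.9,
                          noise_sd = c(hr = 6, rr = 3, spo2 = 1.5, sbp = 8),
                          baseline = c(hr = 85, rr = 18, spo2 = 96, sbp = 120),
                          between_sd = c(hr = 10, rr = 2.5, spo2 = 1.5, sbp = 12),
                          mean_rr = 750,
                          sd_rr = 40,
                          mean_rr_between_sd = 60,
                          effect_scale_sd = 0.25,
                          doc_interval = c(1, 6),
                          missing_rate = 0.05,
                          control_vent_fraction = 0,
                          allow_multi_event = FALSE,
                          seed = 1L) {
  cfg <- list(
    n_admissions = n_admissions, event_fraction = event_fraction,
    dni_fraction = dni_fraction, stay_meanlog = stay_meanlog,
    stay_sdlog = stay_sdlog, min_stay_hours = min_stay_hours,
    ramp_hours = ramp_hours, effect_sizes = effect_sizes,
    rr_variability_shrink = rr_variability_shrink,
    ar_coefficient = ar_coefficient, noise_sd = noise_sd,
    baseline = baseline, between_sd = between_sd,
    mean_rr = mean_rr, sd_rr = sd_rr,
    mean_rr_between_sd = mean_rr_between_sd,
    effect_scale_sd = effect_scale_sd,
    doc_interval = doc_interval, missing_rate = missing_rate,
    control_vent_fraction = control_vent_fraction,
    allow_multi_event = allow_multi_event, seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

channel_names <- function() c("hr", "rr", "spo2", "sbp")

validate_cohort_config <- function(cfg) {
  stop_field <- function(field, why) {
    stop(sprintf("invalid cohort configuration: field '%s' %s", field, why),
         call. = FALSE)
  }
  num1 <- function(field, lo = -Inf, hi = Inf) {
    x <- cfg[[field]]
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      stop_field(field, "must be a finite number")
    }
    if (x < lo || x > hi) {
      stop_field(field, sprintf("must be in [%s, %s]", lo, hi))
    }
  }
  num1("n_admissions", 0)
  if (cfg$n_admissions != floor(cfg$n_admissions)) {
    stop_field("n_admissions", "must be a whole number")
  }
  num1("event_fraction", 0, 1)
  num1("dni_fraction", 0, 1)
  if (cfg$event_fraction + cfg$dni_fraction > 1) {
    stop_field("event_fraction", "plus dni_fraction must be <= 1")
  }
  num1("stay_meanlog"); num1("stay_sdlog", 0)
  num1("min_stay_hours", 0)
  num1("ramp_hours", 1e-9)
  num1("rr_variability_shrink", 1e-9, 1)
  num1("ar_coefficient", 0, 1 - 1e-9)
  num1("mean_rr", 1e-9); num1("sd_rr", 0)
  num1("mean_rr_between_sd", 0); num1("effect_scale_sd", 0)
  num1("missing_rate", 0, 1)
  num1("control_vent_fraction", 0, 1)
  for (field in c("effect_sizes", "noise_sd", "baseline", "between_sd")) {
    x <- cfg[[field]]
    if (!is.numeric(x) || !all(channel_names() %in% names(x))) {
      stop_field(field, "must be numeric with names hr, rr, spo2, sbp")
    }
  }
  if (any(cfg$noise_sd < 0)) stop_field("noise_sd", "must be >= 0")
  if (any(cfg$between_sd < 0)) stop_field("between_sd", "must be >= 0")
  di <- cfg$doc_interval
  if (!is.numeric(di) || length(di) != 2L || di[1] <= 0 || di[2] < di[1]) {
    stop_field("doc_interval", "must be an increasing positive range (hours)")
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L || is.na(cfg$seed)) {
    stop_field("seed", "must be a single integer")
  }
  invisible(cfg)
}

#' Simulate a per-minute vital-sign series
#'
#' Vital signs are sampled once per minute as AR(1) noise around a baseline.
#' When a deterioration is present, channel means shift linearly from 0 to
#' the full effect size over the final `ramp_hours` before the event and
#' hold thereafter. SpO2 is clipped to `[0, 100]`, the other channels to be
#' non-negative.
#'
#' @param duration_min Stay duration in minutes (> 0).
#' @param baseline Named per-channel levels (`hr`, `rr`, `spo2`, `sbp`).
#' @param deterioration `NULL`, or a list with `event_time_min`,
#'   `ramp_hours` and `effect` (named per-channel shifts at event time).
#' @param ar AR(1) coefficient in `[0, 1)`; the innovation SD is scaled so
#'   the stationary marginal SD equals `noise_sd`.
#' @param noise_sd Named per-channel stationary noise SDs (>= 0).
#' @param seed Integer seed.
#'
#' @return A tibble with columns `t_min`, `hr`, `rr`, `spo2`, `sbp`.
#' @export
simulate_vitals <- function(duration_min, baseline, deterioration = NULL,
                            ar = 0.9, noise_sd, seed = 1L) {
  if (duration_min <= 0) stop("duration_min must be > 0", call. = FALSE)
  if (any(noise_sd < 0)) stop("noise_sd must be >= 0", call. = FALSE)
  t_min <- seq(0, floor(duration_min))
  n <- length(t_min)
  withr::with_seed(seed, {
    out <- lapply(channel_names(), function(ch) {
      x <- ar1_noise(n, ar, noise_sd[[ch]])
      mu <- rep(baseline[[ch]], n)
      if (!is.null(deterioration)) {
        mu <- mu + deterioration_shift(
          t_min, deterioration$event_time_min,
          deterioration$ramp_hours, deterioration$effect[[ch]]
        )
      }
      mu + x
    })
  })
  names(out) <- channel_names()
  out$spo2 <- pmin(pmax(out$spo2, 0), 100)
  for (ch in c("hr", "rr", "sbp")) out[[ch]] <- pmax(out[[ch]], 0)
  tibble::tibble(t_min = t_min, hr = out$hr, rr = out$rr,
                 spo2 = out$spo2, sbp = out$sbp)
}

# Stationary AR(1) with marginal SD `sd`; lag-1 autocorrelation = ar.
ar1_noise <- function(n, ar, sd) {
  if (sd == 0) return(numeric(n))
  innov_sd <- sd * sqrt(1 - ar^2)
  if (ar == 0) return(rnorm(n, 0, sd))
  as.numeric(stats::filter(rnorm(n, 0, innov_sd), ar, method = "recursive",
                           init = rnorm(1, 0, sd)))
}

# Linear ramp from 0 (ramp start) to `effect` (event time), held afterwards.
deterioration_shift <- function(t_min, event_time_min, ramp_hours, effect) {
  ramp_min <- ramp_hours * 60
  frac <- (t_min - (event_time_min - ramp_min)) / ramp_min
  effect * pmin(pmax(frac, 0), 1)
}

#' Simulate a beat-to-beat RR-interval series
#'
#' Beat times accumulate from Gaussian RR intervals. When a deterioration is
#' present, the interval SD shrinks linearly to `sd_rr * shrink` at the event
#' time (reduced heart-rate variability), holding thereafter. Intervals are
#' floored at `floor_ms`; the number of floored intervals is attached as the
#' `"n_floored"` attribute.
#'
#' @param duration_min Stay duration in minutes (> 0).
#' @param mean_rr,sd_rr Mean (> 0) and SD (>= 0) of RR intervals, ms.
#' @param deterioration `NULL`, or list with `event_time_min`, `ramp_hours`,
#'   `shrink` (multiplicative SD factor reached at event time).
#' @param seed Integer seed.
#' @param floor_ms Minimum physiologically plausible interval (default 200).
#'
#' @return A tibble with columns `beat_time_min` (strictly increasing, first
#'   beat at 0) and `rr_ms` (`NA` for the first beat).
#' @export
simulate_rr_intervals <- function(duration_min, mean_rr, sd_rr,
                                  deterioration = NULL, seed = 1L,
                                  floor_ms = 200) {
  if (duration_min <= 0) stop("duration_min must be > 0", call. = FALSE)
  if (mean_rr <= 0) stop("mean_rr must be > 0", call. = FALSE)
  if (sd_rr < 0) stop("sd_rr must be >= 0", call. = FALSE)
  duration_ms <- duration_min * 60000
  n <- ceiling(duration_ms / mean_rr * 1.05) + 10
  # SD profile evaluated on the nominal beat schedule; the deviation between
  # nominal and realised beat times is negligible against a multi-hour ramp.
  nominal_t_min <- (seq_len(n) - 1) * mean_rr / 60000
  sds <- rep(sd_rr, n)
  if (!is.null(deterioration)) {
    frac <- deterioration_shift(nominal_t_min, deterioration$event_time_min,
                                deterioration$ramp_hours, 1)
    sds <- sd_rr * (1 - (1 - deterioration$shrink) * frac)
  }
  withr::with_seed(seed, {
    intervals <- rnorm(n, mean_rr, sds)
  })
  n_floored <- sum(intervals < floor_ms)
  intervals <- pmax(intervals, floor_ms)
  beat_time_min <- c(0, cumsum(intervals) / 60000) # first beat at t = 0
  keep <- beat_time_min <= duration_min
  beat_time_min <- beat_time_min[keep]
  rr_ms <- c(NA_real_, intervals)[keep]
  out <- tibble::tibble(beat_time_min = beat_time_min, rr_ms = rr_ms)
  attr(out, "n_floored") <- n_floored
  out
}

#' Simulate ventilator respiratory-rate flowsheet documentation
#'
#' Respiratory therapists chart the ventilator respiratory rate only while a
#' patient is ventilated, typically every 1-6 hours. Entries are placed only
#' inside the ground-truth ventilation epochs: one at each epoch boundary,
#' with intermediate gaps drawn uniformly from `doc_interval`.
#'
#' @param truth_epochs Tibble with `start_min`, `end_min`: disjoint,
#'   increasing ground-truth ventilation epochs.
#' @param doc_interval Length-2 range of documentation gaps, hours.
#' @param seed Integer seed.
#'
#' @return A tibble with `t_min` and `vent_rr` (set ventilator rate,
#'   breaths/min), sorted by time; zero rows when there are no epochs.
#' @export
simulate_flowsheet <- function(truth_epochs, doc_interval = c(1, 6),
                               seed = 1L) {
  if (is.null(truth_epochs) || nrow(truth_epochs) == 0) {
    return(tibble::tibble(t_min = numeric(), vent_rr = numeric()))
  }
  ep <- truth_epochs[order(truth_epochs$start_min), , drop = FALSE]
  if (nrow(ep) > 1 && any(ep$start_min[-1] < ep$end_min[-nrow(ep)])) {
    stop("truth ventilation epochs overlap", call. = FALSE)
  }
  gap_range_min <- doc_interval * 60
  withr::with_seed(seed, {
    times <- lapply(seq_len(nrow(ep)), function(i) {
      s <- ep$start_min[i]; e <- ep$end_min[i]
      ts <- s
      repeat {
        nxt <- ts[length(ts)] + runif(1, gap_range_min[1], gap_range_min[2])
        if (nxt >= e) break
        ts <- c(ts, nxt)
      }
      unique(c(ts, e))
    })
    times <- unlist(times)
    vent_rr <- round(runif(length(times), 12, 28))
  })
  tibble::tibble(t_min = times, vent_rr = vent_rr)
}

#' Generate a synthetic ICU cohort with ground truth
#'
#' Produces one [AdmissionRecord][generate_cohort] per admission: vital
#' signs, RR intervals, flowsheet documentation of mechanical ventilation,
#' the (test-only) ground-truth ventilation epochs, the event time for
#' admissions that progress to emergent intubation, and the DNI flag.
#' Event times are drawn uniformly in `[24 h, duration]`; ground-truth
#' ventilation starts exactly at the event time and runs to the end of
#' stay. Controls are never ventilated unless `control_vent_fraction > 0`.
#'
#' @param config A [cohort_config()].
#'
#' @return A list of class `"icu_cohort"`; each element is a list of class
#'   `"admission_record"` with fields `admission_id`, `duration_min`,
#'   `event_time_min` (`NA` for controls), `event_times_min`, `dni`,
#'   `vitals`, `rr_intervals`, `flowsheet`, `truth_vent_epochs`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_admissions
  if (n == 0) return(structure(list(), class = "icu_cohort"))
  n_event <- round(n * config$event_fraction)
  n_dni <- round(n * config$dni_fraction)

  withr::with_seed(config$seed, {
    status <- rep("control", n)
    ord <- sample.int(n)
    status[ord[seq_len(n_event)]] <- "event"
    if (n_dni > 0) status[ord[n_event + seq_len(n_dni)]] <- "dni"

    records <- lapply(seq_len(n), function(i) {
      dur_h <- max(rlnorm(1, config$stay_meanlog, config$stay_sdlog),
                   config$min_stay_hours)
      is_event <- status[i] == "event"
      if (is_event) dur_h <- max(dur_h, 26)
      duration_min <- round(dur_h * 60)

      event_times <- numeric(0)
      truth <- tibble::tibble(start_min = numeric(), end_min = numeric())
      if (is_event) {
        event_times <- round(runif(1, 24 * 60, duration_min))
        vent_end <- duration_min
        if (config$allow_multi_event && runif(1) < 0.1 &&
            duration_min - event_times[1] > 18 * 60) {
          # extubated after 6-12 h, second event at least 4 h later
          vent_end <- event_times[1] + round(runif(1, 6, 12) * 60)
          t2_lo <- vent_end + 4 * 60
          if (t2_lo < duration_min) {
            event_times <- c(event_times, round(runif(1, t2_lo, duration_min)))
            truth <- tibble::tibble(
              start_min = event_times, end_min = c(vent_end, duration_min)
            )
          } else {
            vent_end <- duration_min
          }
        }
        if (nrow(truth) == 0) {
          truth <- tibble::tibble(start_min = event_times[1],
                                  end_min = vent_end)
        }
      } else if (config$control_vent_fraction > 0 &&
                 runif(1) < config$control_vent_fraction &&
                 duration_min > 12 * 60) {
        s <- runif(1, 0, duration_min - 6 * 60)
        truth <- tibble::tibble(
          start_min = round(s),
          end_min = round(min(s + runif(1, 6, 24) * 60, duration_min))
        )
      }

      # per-admission resting physiology
      base_i <- config$baseline +
        rnorm(length(config$baseline), 0, config$between_sd[names(config$baseline)])
      base_i["spo2"] <- min(base_i["spo2"], 100)
      mean_rr_i <- max(config$mean_rr + rnorm(1, 0, config$mean_rr_between_sd),
                       300)

      det_vitals <- det_rr <- NULL
      if (is_event) {
        scale_i <- exp(rnorm(1, 0, config$effect_scale_sd))
        det_vitals <- list(event_time_min = event_times[1],
                           ramp_hours = config$ramp_hours,
                           effect = config$effect_sizes * scale_i)
        det_rr <- list(event_time_min = event_times[1],
                       ramp_hours = config$ramp_hours,
                       shrink = config$rr_variability_shrink)
      }
      seeds <- sample.int(.Machine$integer.max, 3)
      vitals <- simulate_vitals(duration_min, base_i, det_vitals,
                                config$ar_coefficient, config$noise_sd,
                                seed = seeds[1])
      if (config$missing_rate > 0) {
        for (ch in channel_names()) {
          drop <- runif(nrow(vitals)) < config$missing_rate
          vitals[[ch]][drop] <- NA_real_
        }
      }
      rr <- simulate_rr_intervals(duration_min, mean_rr_i, config$sd_rr,
                                  det_rr, seed = seeds[2])
      flow <- simulate_flowsheet(truth, config$doc_interval, seed = seeds[3])

      structure(list(
        admission_id = sprintf("A%04d", i),
        duration_min = duration_min,
        event_time_min = if (is_event) event_times[1] else NA_real_,
        event_times_min = event_times,
        dni = status[i] == "dni",
        vitals = vitals,
        rr_intervals = rr,
        flowsheet = flow,
        truth_vent_epochs = truth
      ), class = "admission_record")
    })
  })
  structure(records, class = "icu_cohort")
}

#' @export
print.icu_cohort <- function(x, ...) {
  n_event <- sum(vapply(x, function(r) !is.na(r$event_time_min), logical(1)))
  n_dni <- sum(vapply(x, function(r) r$dni, logical(1)))
  cat(sprintf("<icu_cohort> %d admissions: %d event, %d DNI, %d control\n",
              length(x), n_event, n_dni, length(x) - n_event - n_dni))
  invisible(x)
}

#' Admissions summary table of a cohort
#'
#' @param cohort An `"icu_cohort"`.
#' @return Tibble with `admission_id`, `duration_min`, `event_time_min`,
#'   `dni`.
#' @export
cohort_admissions <- function(cohort) {
  tibble::tibble(
    admission_id = vapply(cohort, `[[`, character(1), "admission_id"),
    duration_min = vapply(cohort, `[[`, numeric(1), "duration_min"),
    event_time_min = vapply(cohort, `[[`, numeric(1), "event_time_min"),
    dni = vapply(cohort, `[[`, logical(1), "dni")
  )
}
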