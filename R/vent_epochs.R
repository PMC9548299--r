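#' Rules for reconstructing ventilation epochs
#'
#' Mechanical ventilation is inferred from ventilator respiratory-rate
#' flowsheet entries: an epoch runs from the first to the last entry of a
#' group; groups are split where consecutive entries are more than
#' `split_gap_hours` apart (strictly greater), and an isolated entry opens
#' an epoch of `isolated_hours`.
#'
#' @param split_gap_hours Gap beyond which consecutive entries start a new
#'   epoch (default 16 h).
#' @param isolated_hours Duration assigned to an isolated entry (default 1 h).
#' @return List of class `"epoch_rules"`.
#' @export
epoch_rules <- function(split_gap_hours = 16, isolated_hours = 1) {
  if (split_gap_hours <= 0 || isolated_hours <= 0) {
    stop("epoch rules must be positive durations", call. = FALSE)
  }
  structure(list(split_gap_hours = split_gap_hours,
                 isolated_hours = isolated_hours),
            class = "epoch_rules")
}

entry_times <- function(entries) {
  if (is.numeric(entries)) return(entries)
  if (is.data.frame(entries)) {
    if ("t_min" %in% names(entries)) return(entries$t_min)
    if ("time" %in% names(entries)) return(entries$time)
  }
  stop("flowsheet entries must be numeric times or have a t_min column",
       call. = FALSE)
}

#' Build ventilation epochs from flowsheet entries
#'
#' @param entries Flowsheet entries: a numeric vector of times
#'   (minutes from admission) or a data frame with a `t_min` column.
#'   Sorted internally.
#' @param rules An [epoch_rules()].
#' @return Tibble with `start_min`, `end_min`: disjoint, sorted epochs.
#'   A group of entries all within `split_gap_hours` of their neighbours
#'   spans first-to-last entry; a singleton spans `isolated_hours`.
#' @export
build_epochs <- function(entries, rules = epoch_rules()) {
  t <- sort(unique(entry_times(entries)))
  if (length(t) == 0) {
    return(tibble::tibble(start_min = numeric(), end_min = numeric()))
  }
  if (any(t < 0)) stop("flowsheet entry times must be >= 0", call. = FALSE)
  split_min <- rules$split_gap_hours * 60
  grp <- cumsum(c(1, diff(t) > split_min))
  starts <- tapply(t, grp, min)
  ends <- tapply(t, grp, max)
  iso <- ends == starts
  ends[iso] <- starts[iso] + rules$isolated_hours * 60
  tibble::tibble(start_min = as.numeric(starts), end_min = as.numeric(ends))
}

#' Reconcile ventilation epochs with known emergent-intubation times
#'
#' Verified events must begin a ventilation epoch exactly at the event
#' time. When an event falls strictly inside a reconstructed epoch, the
#' epoch is split: the earlier piece ends at the last flowsheet entry
#' before the event (the inferred extubation) and the later piece starts
#' at the event time. An event outside every epoch opens a new epoch
#' ending at the next flowsheet entry, or after `isolated_hours` when no
#' entry follows.
#'
#' @param epochs Tibble from [build_epochs()].
#' @param entries The flowsheet entries the epochs were built from.
#' @param event_times Sorted numeric event times (minutes), each >= 0.
#' @param rules An [epoch_rules()].
#' @param admission_end Optional stay duration; an event beyond it errors.
#' @return Tibble `start_min`, `end_min`; disjoint, sorted, with an epoch
#'   starting exactly at every event time.
#' @export
split_at_intubation <- function(epochs, entries, event_times,
                                rules = epoch_rules(),
                                admission_end = NULL) {
  event_times <- sort(event_times)
  if (length(event_times) == 0) return(epochs)
  if (any(event_times < 0)) stop("event times must be >= 0", call. = FALSE)
  if (!is.null(admission_end) && any(event_times > admission_end)) {
    stop("event time after admission end", call. = FALSE)
  }
  t_entries <- sort(unique(entry_times(entries)))
  iso_min <- rules$isolated_hours * 60
  ivs <- Map(c, epochs$start_min, epochs$end_min)

  for (ev in event_times) {
    hit <- which(vapply(ivs, function(iv) iv[1] < ev & ev < iv[2], logical(1)))
    starts_here <- any(vapply(ivs, function(iv) iv[1] == ev, logical(1)))
    if (starts_here) next
    if (length(hit)) {
      iv <- ivs[[hit[1]]]
      prev <- t_entries[t_entries < ev & t_entries > iv[1]]
      left <- if (length(prev)) {
        # extubation at the latest flowsheet entry preceding the event
        c(iv[1], max(prev))
      } else if (iv[1] %in% t_entries) {
        # no internal entry: isolated-duration reading of the opening entry
        c(iv[1], min(iv[1] + iso_min, ev))
      } else {
        # epoch opened by an earlier event: censor through to this one
        c(iv[1], ev)
      }
      pieces <- Filter(function(p) p[1] < p[2], list(left, c(ev, iv[2])))
      ivs <- c(ivs[-hit[1]], pieces)
    } else {
      nxt <- t_entries[t_entries > ev]
      end <- if (length(nxt)) min(nxt) else ev + iso_min
      ivs <- c(ivs, list(c(ev, end)))
    }
    ivs <- ivs[order(vapply(ivs, `[[`, numeric(1), 1))]
  }

  # normalise: union overlapping intervals, then re-cut at event times so
  # every event still begins an epoch (ties broken toward longer censoring)
  merged <- list()
  for (iv in ivs) {
    k <- length(merged)
    if (k && iv[1] <= merged[[k]][2]) {
      merged[[k]][2] <- max(merged[[k]][2], iv[2])
    } else {
      merged[[length(merged) + 1]] <- iv
    }
  }
  out <- list()
  for (iv in merged) {
    inside <- event_times[event_times > iv[1] & event_times < iv[2]]
    cur <- iv
    for (ev in inside) {
      prev <- t_entries[t_entries < ev & t_entries > cur[1]]
      # no entry between: keep the whole pre-event stretch censored
      # (ties broken toward longer censoring)
      left_end <- if (length(prev)) max(prev) else ev
      if (left_end > cur[1]) out[[length(out) + 1]] <- c(cur[1], left_end)
      cur <- c(ev, cur[2])
    }
    out[[length(out) + 1]] <- cur
  }
  tibble::tibble(
    start_min = vapply(out, `[[`, numeric(1), 1),
    end_min = vapply(out, `[[`, numeric(1), 2)
  )
}

#' Censor mask for feature epochs
#'
#' Epochs are censored while the patient is mechanically ventilated
#' (membership closed on both ends: a time exactly at intubation or
#' extubation is censored) and for all of a DNI admission.
#'
#' @param epoch_times Sorted numeric times (minutes) to classify.
#' @param vent_epochs Tibble with `start_min`, `end_min`.
#' @param dni Logical DNI flag for the admission.
#' @return Logical vector, `TRUE` = censored.
#' @export
censor_mask <- function(epoch_times, vent_epochs, dni = FALSE) {
  if (isTRUE(dni)) return(rep(TRUE, length(epoch_times)))
  mask <- rep(FALSE, length(epoch_times))
  if (!is.null(vent_epochs) && nrow(vent_epochs)) {
    for (i in seq_len(nrow(vent_epochs))) {
      mask <- mask | (epoch_times >= vent_epochs$start_min[i] &
                        epoch_times <= vent_epochs$end_min[i])
    }
  }
  mask
}
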