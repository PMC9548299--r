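#' Write a cohort to delimited tables
#'
#' Writes `admissions.csv`, `vitals.csv`, `rr_intervals.csv`,
#' `flowsheet.csv` and `truth_epochs.csv` (UTF-8, header row, missing
#' values as empty fields) to a directory.
#'
#' @param cohort An `"icu_cohort"`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  adm <- cohort_admissions(cohort)
  readr::write_csv(adm, file.path(dir, "admissions.csv"), na = "")
  bind_with_id <- function(field) {
    do.call(rbind, lapply(cohort, function(rec) {
      x <- rec[[field]]
      if (is.null(x) || nrow(x) == 0) return(NULL)
      tibble::add_column(x, admission_id = rec$admission_id, .before = 1)
    }))
  }
  readr::write_csv(bind_with_id("vitals"), file.path(dir, "vitals.csv"),
                   na = "")
  readr::write_csv(bind_with_id("rr_intervals"),
                   file.path(dir, "rr_intervals.csv"), na = "")
  flow <- bind_with_id("flowsheet")
  if (is.null(flow)) {
    flow <- tibble::tibble(admission_id = character(), t_min = numeric(),
                           vent_rr = numeric())
  }
  readr::write_csv(flow, file.path(dir, "flowsheet.csv"), na = "")
  truth <- bind_with_id("truth_vent_epochs")
  if (is.null(truth)) {
    truth <- tibble::tibble(admission_id = character(),
                            start_min = numeric(), end_min = numeric())
  }
  readr::write_csv(truth, file.path(dir, "truth_epochs.csv"), na = "")
  invisible(dir)
}

#' Read a cohort from delimited tables
#'
#' Inverse of [write_cohort()].
#'
#' @param dir Directory holding the cohort tables.
#' @return An `"icu_cohort"`.
#' @export
read_cohort <- function(dir) {
  rd <- function(name) {
    readr::read_csv(file.path(dir, name), show_col_types = FALSE,
                    progress = FALSE)
  }
  adm <- rd("admissions.csv")
  vitals <- rd("vitals.csv")
  rr <- rd("rr_intervals.csv")
  flow <- rd("flowsheet.csv")
  truth <- rd("truth_epochs.csv")
  records <- lapply(seq_len(nrow(adm)), function(i) {
    id <- adm$admission_id[i]
    ev <- adm$event_time_min[i]
    structure(list(
      admission_id = id,
      duration_min = adm$duration_min[i],
      event_time_min = ev,
      event_times_min = if (is.na(ev)) numeric(0) else ev,
      dni = adm$dni[i],
      vitals = vitals[vitals$admission_id == id,
                      c("t_min", "hr", "rr", "spo2", "sbp")],
      rr_intervals = rr[rr$admission_id == id,
                        c("beat_time_min", "rr_ms")],
      flowsheet = flow[flow$admission_id == id, c("t_min", "vent_rr")],
      truth_vent_epochs = truth[truth$admission_id == id,
                                c("start_min", "end_min")]
    ), class = "admission_record")
  })
  structure(records, class = "icu_cohort")
}
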