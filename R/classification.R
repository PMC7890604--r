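## Temporal classification of the structured diagnosis relative to the
## computed diagnosis, and the survival cohort.
##
## Categories (for patients WITH a computed diagnosis; others are outside
## all denominators):
##   pre_existing  dx strictly before the first signal
##   early         first signal <= dx < second signal
##   eventual      dx on or after the second signal (event, duration =
##                 dx - second signal, in days)
##   never         no structured dx (censored at most recent encounter,
##                 duration = last encounter - second signal, floored at 0)
## Boundary ties read "prior to"/"after" strictly so the partition is
## exhaustive: dx on the first-signal day is early; dx on the
## second-signal day is eventual with duration 0.

#' Classify patients with a computed diagnosis
#'
#' Joins computed diagnoses with the (optional) first structured diagnosis
#' and the last encounter date, assigns the temporal category, and derives
#' duration/event for survival analysis. Never-diagnosed patients whose last
#' encounter precedes the second signal get duration floored at 0 (with a
#' warning); patients with no encounter at all are floored likewise.
#'
#' @param computed data.table from [compute_diagnosis()] (`patient_id`,
#'   `first_signal_date`, `second_signal_date`).
#' @param structured data.table from [first_structured_dx()], or `NULL`.
#' @param last_encounter data.table (`patient_id`, `last_encounter_date`),
#'   e.g. from [last_encounters()].
#' @param condition Condition label carried into the output.
#' @return data.table with one row per computed-diagnosis patient: columns
#'   `patient_id`, `condition`, `first_signal_date`, `second_signal_date`,
#'   `first_dx_date`, `dx_source`, `last_encounter_date`, `category`,
#'   `duration_days` (NA for pre_existing/early), `event`.
#' @export
classify_patients <- function(computed, structured, last_encounter,
                              condition = NA_character_) {
  cls <- data.table::copy(computed)
  if (!is.null(structured) && nrow(structured)) {
    cls <- merge(cls, structured[, .(patient_id, first_dx_date, dx_source)],
                 by = "patient_id", all.x = TRUE)
  } else {
    cls[, `:=`(first_dx_date = as.Date(NA), dx_source = NA_character_)]
  }
  if (!is.null(last_encounter) && nrow(last_encounter)) {
    cls <- merge(cls, last_encounter[, .(patient_id, last_encounter_date)],
                 by = "patient_id", all.x = TRUE)
  } else {
    cls[, last_encounter_date := as.Date(NA)]
  }
  cls[, condition := condition]
  cls[, category := data.table::fcase(
    is.na(first_dx_date), "never",
    first_dx_date < first_signal_date, "pre_existing",
    first_dx_date < second_signal_date, "early",
    default = "eventual"
  )]
  cls[, duration_days := NA_integer_]
  cls[category == "eventual",
      duration_days := as.integer(first_dx_date - second_signal_date)]
  # internal assertion: eventual duration nonnegative by construction
  stopifnot(all(cls[category == "eventual", duration_days] >= 0L))
  cens <- cls$category == "never"
  raw_cens <- as.integer(cls$last_encounter_date[cens] - cls$second_signal_date[cens])
  raw_cens[is.na(raw_cens)] <- 0L
  n_floor <- sum(raw_cens < 0L)
  if (n_floor > 0) {
    warning(n_floor, " never-diagnosed patient(s) with last encounter before ",
            "the second signal; duration floored at 0", call. = FALSE)
    raw_cens[raw_cens < 0L] <- 0L
  }
  cls[cens, duration_days := raw_cens]
  cls[, event := category == "eventual"]
  data.table::setcolorder(cls, c("patient_id", "condition", "first_signal_date",
                                 "second_signal_date", "first_dx_date", "dx_source",
                                 "last_encounter_date", "category", "duration_days",
                                 "event"))
  data.table::setkey(cls, patient_id)
  cls[]
}

#' Last encounter per patient
#'
#' The date of the patient's most recent encounter with the health system:
#' the maximum encounter date on or before the diagnosis cutoff. The
#' encounter table is authoritative; measurement dates without encounter
#' rows do not extend follow-up.
#'
#' @param encounters Encounter record table.
#' @param window A [study_window()].
#' @return data.table (`patient_id`, `last_encounter_date`).
#' @export
last_encounters <- function(encounters, window) {
  e <- filter_window(encounters, window, "diagnosis", date_col = "encounter_date")
  e[, .(last_encounter_date = max(encounter_date)), by = patient_id]
}

#' Restrict classifications to the time-to-diagnosis cohort
#'
#' Patients with a pre-existing (prior to first signal) or early (between
#' first and second signal) structured diagnosis are excluded; only
#' `eventual` and `never` remain.
#'
#' @param cls Classification table from [classify_patients()].
#' @return Filtered classification table.
#' @export
exclusion_filter <- function(cls) {
  out <- cls[category %in% c("eventual", "never")]
  if (nrow(cls) > 0 && nrow(out) == 0) {
    warning("survival cohort is empty after exclusions", call. = FALSE)
  }
  out
}
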