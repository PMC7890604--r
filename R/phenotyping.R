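## Rule-based (computed) phenotyping: per-day signal detection and the
## two-signals-at-least-30-days-apart rule.
##
## A "signal of disease" is a single day's aggregated measurement meeting the
## condition's threshold rule. When several measurements fall on one day the
## MINIMUM is taken first, so a day counts only if even its most favorable
## reading is abnormal (conservative ascertainment). A computed diagnosis is
## dated at the second signal: the earliest date with some earlier signal at
## least `min_separation_days` before it.

#' Condition specification
#'
#' Bundles the signal rule for one condition. Defaults:
#' \describe{
#'   \item{HTN}{outpatient blood pressure, daily minimum systolic >= 140 mmHg
#'     OR daily minimum diastolic >= 90 mmHg (minima taken independently).}
#'   \item{HLD}{LDL cholesterol >= 130 mg/dL, LOINC 13457-7 or 18262-6.}
#'   \item{DM}{hemoglobin A1c >= 6.5 %, LOINC 4548-4.}
#' }
#' All thresholds are inclusive. Institution-local lab codes can be unioned
#' in via `local_codes`.
#'
#' @param name One of `"HTN"`, `"HLD"`, `"DM"`.
#' @param local_codes Extra lab code strings accepted alongside LOINC.
#' @param min_separation_days Minimum days between the two qualifying
#'   signals (default 30).
#' @param systolic_threshold,diastolic_threshold,lab_threshold Override the
#'   default thresholds.
#' @return An object of class `condition_spec`.
#' @export
condition_spec <- function(name = c("HTN", "HLD", "DM"), local_codes = character(),
                           min_separation_days = 30L,
                           systolic_threshold = 140, diastolic_threshold = 90,
                           lab_threshold = NULL) {
  name <- match.arg(name)
  stopifnot(min_separation_days >= 0)
  spec <- switch(name,
    HTN = list(name = "HTN", kind = "vital", outpatient_only = TRUE,
               systolic_threshold = systolic_threshold,
               diastolic_threshold = diastolic_threshold),
    HLD = list(name = "HLD", kind = "lab",
               lab_threshold = lab_threshold %||% 130,
               loinc = c("13457-7", "18262-6")),
    DM  = list(name = "DM", kind = "lab",
               lab_threshold = lab_threshold %||% 6.5,
               loinc = "4548-4")
  )
  if (spec$kind == "lab") {
    spec$codes <- unique(c(spec$loinc, local_codes))
    stopifnot(spec$lab_threshold > 0, length(spec$codes) > 0)
  } else {
    stopifnot(spec$systolic_threshold > 0, spec$diastolic_threshold > 0)
  }
  spec$min_separation_days <- as.integer(min_separation_days)
  structure(spec, class = "condition_spec")
}

#' Default specifications for the three conditions
#' @inheritParams condition_spec
#' @return Named list of [condition_spec()] objects.
#' @export
default_condition_specs <- function(min_separation_days = 30L) {
  setNames(lapply(conditions(), condition_spec,
                  min_separation_days = min_separation_days), conditions())
}

#' Aggregate measurements to one observation per patient-day
#'
#' Applies the same-day minimum rule. For HTN, only outpatient readings are
#' considered, and the daily minima of systolic and diastolic are computed
#' independently (possibly from different readings). For lab conditions the
#' minimum numeric result over the condition's code set that day is taken.
#' Rows with missing values for the needed fields are ignored. The result is
#' invariant to input row order.
#'
#' @param vitals,labs Typed record tables (see [read_cdm_tables()]); the one
#'   the condition does not use may be `NULL`.
#' @param spec A [condition_spec()].
#' @return data.table with one row per (patient_id, date): columns
#'   `min_systolic`/`min_diastolic` for HTN, `min_value` for lab conditions.
#' @export
aggregate_daily <- function(vitals, labs, spec) {
  stopifnot(inherits(spec, "condition_spec"))
  if (spec$kind == "vital") {
    v <- if (is.null(vitals) || nrow(vitals) == 0) {
      empty_cdm_tables()$vital
    } else {
      vitals[encounter_setting == "outpatient" &
               (!is.na(systolic) | !is.na(diastolic))]
    }
    if (nrow(v) == 0) {
      return(data.table(patient_id = character(), date = as.Date(character()),
                        min_systolic = numeric(), min_diastolic = numeric(),
                        key = c("patient_id", "date")))
    }
    daily <- v[, .(
      min_systolic = if (all(is.na(systolic))) NA_real_ else min(systolic, na.rm = TRUE),
      min_diastolic = if (all(is.na(diastolic))) NA_real_ else min(diastolic, na.rm = TRUE)
    ), by = .(patient_id, date = measure_date)]
  } else {
    l <- if (is.null(labs) || nrow(labs) == 0) {
      empty_cdm_tables()$lab_result
    } else {
      labs[code %in% spec$codes & !is.na(value)]
    }
    if (nrow(l) == 0) {
      return(data.table(patient_id = character(), date = as.Date(character()),
                        min_value = numeric(), key = c("patient_id", "date")))
    }
    daily <- l[, .(min_value = min(value)), by = .(patient_id, date = specimen_date)]
  }
  data.table::setkey(daily, patient_id, date)
  daily[]
}

#' Detect per-day disease signals
#'
#' A day is a signal iff the daily aggregated value(s) meet the condition's
#' inclusive threshold rule: HTN `min_systolic >= 140 OR min_diastolic >= 90`;
#' HLD `min_value >= 130`; DM `min_value >= 6.5`.
#'
#' @param daily Output of [aggregate_daily()].
#' @param spec A [condition_spec()].
#' @return data.table (`patient_id`, `date`) of signal days, sorted, unique.
#' @export
detect_signals <- function(daily, spec) {
  stopifnot(inherits(spec, "condition_spec"))
  if (spec$kind == "vital") {
    hit <- daily[(!is.na(min_systolic) & min_systolic >= spec$systolic_threshold) |
                 (!is.na(min_diastolic) & min_diastolic >= spec$diastolic_threshold)]
  } else {
    hit <- daily[min_value >= spec$lab_threshold]
  }
  out <- unique(hit[, .(patient_id, date)])
  data.table::setkey(out, patient_id, date)
  out[]
}

#' Compute rule-based diagnoses from signal series
#'
#' A patient has a computed diagnosis iff two signal dates at least
#' `min_separation_days` apart exist. `first_signal_date` is the earliest
#' signal overall; `second_signal_date` (the computed-diagnosis date) is the
#' earliest date `d` such that some earlier signal `d'` satisfies
#' `d - d' >= min_separation_days`. Because `first_signal_date` is the series
#' minimum, this is the earliest signal at least `min_separation_days` after
#' it.
#'
#' @param signals data.table (`patient_id`, `date`) from [detect_signals()].
#' @param spec A [condition_spec()] (only `min_separation_days` is used).
#' @return data.table (`patient_id`, `first_signal_date`,
#'   `second_signal_date`), one row per qualifying patient.
#' @export
compute_diagnosis <- function(signals, spec) {
  sep <- spec$min_separation_days
  if (nrow(signals) == 0) {
    return(data.table(patient_id = character(),
                      first_signal_date = as.Date(character()),
                      second_signal_date = as.Date(character())))
  }
  s <- unique(signals[, .(patient_id, date)])
  out <- s[, {
    first <- min(date)
    qual <- date[as.integer(date - first) >= sep & date > first]
    if (length(qual)) {
      .(first_signal_date = first, second_signal_date = min(qual))
    } else {
      .(first_signal_date = as.Date(NA), second_signal_date = as.Date(NA))
    }
  }, by = patient_id]
  out <- out[!is.na(second_signal_date)]
  data.table::setkey(out, patient_id)
  out[]
}

#' @export
print.condition_spec <- function(x, ...) {
  if (x$kind == "vital") {
    cat(sprintf("%s: outpatient BP, min systolic >= %g or min diastolic >= %g mmHg; ",
                x$name, x$systolic_threshold, x$diastolic_threshold))
  } else {
    cat(sprintf("%s: lab codes {%s}, min value >= %g; ",
                x$name, paste(x$codes, collapse = ", "), x$lab_threshold))
  }
  cat(sprintf("two signals >= %d days apart\n", x$min_separation_days))
  invisible(x)
}
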