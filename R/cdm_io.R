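## PCORnet-CDM-shaped table I/O and study-window filtering.
##
## The pipeline consumes five tables (demographic, encounter, diagnosis,
## vital, lab_result) as CSV extracts shaped like PCORnet CDM v3.1. Column
## names are config-driven so non-CDM extracts can be adapted; defaults are
## the CDM v3.1 names. All dates are handled at day granularity: timestamps
## are truncated to dates on load.

#' Study window
#'
#' Defines the analysis window: measurements (vitals, labs) are honored
#' through `measurement_cutoff`, diagnosis records and encounters through
#' `diagnosis_cutoff`. The gap between the two cutoffs gives every computed
#' diagnosis a minimum follow-up period in which a structured diagnosis could
#' be recorded. Defaults reproduce the reference configuration: data from
#' 2012-01-01, measurements through 2018-08-11, diagnoses and encounters
#' through 2019-02-10 (a 26-week gap).
#'
#' @param data_start First date of usable data.
#' @param measurement_cutoff Last date of usable measurements.
#' @param diagnosis_cutoff Last date of usable diagnoses/encounters.
#' @return An object of class `study_window`.
#' @export
study_window <- function(data_start = "2012-01-01",
                         measurement_cutoff = "2018-08-11",
                         diagnosis_cutoff = "2019-02-10") {
  w <- list(
    data_start = as.Date(data_start),
    measurement_cutoff = as.Date(measurement_cutoff),
    diagnosis_cutoff = as.Date(diagnosis_cutoff)
  )
  if (anyNA(unlist(w))) stop("study_window: unparseable date", call. = FALSE)
  if (!(w$data_start < w$measurement_cutoff &&
        w$measurement_cutoff < w$diagnosis_cutoff)) {
    stop("study_window requires data_start < measurement_cutoff < diagnosis_cutoff",
         call. = FALSE)
  }
  structure(w, class = "study_window")
}

#' Default CDM v3.1 column map
#'
#' Maps the pipeline's canonical field names to source-extract column names,
#' and carries the vocabulary maps for diagnosis source (`OD`/`BI`/`CL` are
#' labeled provider/billing/claims), ICD code type (`09`/`10`), and the
#' encounter-type codes treated as outpatient (default `AV`, `OA`).
#'
#' @param outpatient_codes Encounter-type codes mapped to "outpatient".
#' @param inpatient_codes,emergency_codes Codes for the other named settings;
#'   anything else maps to "other".
#' @return A list, one element per table, plus vocabulary maps.
#' @export
cdm_colmap <- function(outpatient_codes = c("AV", "OA"),
                       inpatient_codes = c("IP", "EI", "IS"),
                       emergency_codes = "ED") {
  list(
    demographic = c(patient_id = "PATID", birth_date = "BIRTH_DATE", sex = "SEX"),
    encounter   = c(patient_id = "PATID", encounter_date = "ADMIT_DATE",
                    enc_type = "ENC_TYPE"),
    diagnosis   = c(patient_id = "PATID", dx_date = "ADMIT_DATE", code = "DX",
                    code_type = "DX_TYPE", source = "DX_SOURCE"),
    vital       = c(patient_id = "PATID", measure_date = "MEASURE_DATE",
                    systolic = "SYSTOLIC", diastolic = "DIASTOLIC",
                    enc_type = "ENC_TYPE"),
    lab_result  = c(patient_id = "PATID", specimen_date = "SPECIMEN_DATE",
                    code = "LAB_LOINC", value = "RESULT_NUM"),
    source_map  = c(OD = "provider", BI = "billing", CL = "claims"),
    dx_type_map = c(`09` = "ICD9CM", `10` = "ICD10CM",
                    ICD9CM = "ICD9CM", ICD10CM = "ICD10CM"),
    outpatient_codes = outpatient_codes,
    inpatient_codes = inpatient_codes,
    emergency_codes = emergency_codes
  )
}

.enc_setting <- function(enc_type, colmap) {
  out <- rep("other", length(enc_type))
  out[enc_type %in% colmap$outpatient_codes] <- "outpatient"
  out[enc_type %in% colmap$inpatient_codes] <- "inpatient"
  out[enc_type %in% colmap$emergency_codes] <- "emergency"
  out
}

.parse_date <- function(x) {
  # day granularity: truncate timestamps ("2015-01-02 10:11:12" -> date)
  as.Date(substr(trimws(as.character(x)), 1L, 10L), format = "%Y-%m-%d")
}

.require_cols <- function(dt, cols, table, file) {
  missing <- setdiff(unname(cols), names(dt))
  if (length(missing)) {
    stop(sprintf("table '%s' (%s): missing required column(s): %s",
                 table, file, paste(missing, collapse = ", ")), call. = FALSE)
  }
}

#' Read CDM-shaped tables
#'
#' Reads the named CSV files into typed record tables. Rows with unparseable
#' dates, non-numeric values where numeric is required, empty codes, or
#' unmapped diagnosis-source strings are dropped and counted in the load
#' report (`attr(x, "load_report")`), never silently coerced. Vital-sign
#' values outside sanity bounds (0 < mmHg < 400) and negative/non-finite lab
#' values are likewise dropped and counted.
#'
#' @param paths Named list/vector of file paths; recognized names are
#'   `demographic`, `encounter`, `diagnosis`, `condition`, `vital`,
#'   `lab_result`. A `condition` table, if given, is read with the diagnosis
#'   schema and appended to the diagnosis records.
#' @param colmap Column map from [cdm_colmap()].
#' @param verbose Log row counts per table.
#' @return A list of data.tables of class `cdm_tables` with elements
#'   `demographic`, `encounter`, `diagnosis`, `vital`, `lab_result`.
#' @export
read_cdm_tables <- function(paths, colmap = cdm_colmap(), verbose = FALSE) {
  paths <- as.list(paths)
  for (p in unlist(paths)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  report <- list()
  note <- function(table, reason, n) {
    if (n > 0) report[[table]][[reason]] <<- (report[[table]][[reason]] %||% 0L) + as.integer(n)
  }
  read_raw <- function(path) {
    data.table::fread(path, colClasses = "character", na.strings = c("", "NA"))
  }

  out <- empty_cdm_tables()

  if (!is.null(paths$demographic)) {
    m <- colmap$demographic
    raw <- read_raw(paths$demographic)
    .require_cols(raw, m[c("patient_id")], "demographic", paths$demographic)
    dt <- data.table(
      patient_id = raw[[m["patient_id"]]],
      birth_date = if (m["birth_date"] %in% names(raw)) .parse_date(raw[[m["birth_date"]]]) else as.Date(NA),
      sex = if (m["sex"] %in% names(raw)) raw[[m["sex"]]] else NA_character_
    )
    bad <- is.na(dt$patient_id)
    note("demographic", "missing_patient_id", sum(bad))
    out$demographic <- dt[!bad]
  }

  if (!is.null(paths$encounter)) {
    m <- colmap$encounter
    raw <- read_raw(paths$encounter)
    .require_cols(raw, m[c("patient_id", "encounter_date")], "encounter", paths$encounter)
    dt <- data.table(
      patient_id = raw[[m["patient_id"]]],
      encounter_date = .parse_date(raw[[m["encounter_date"]]]),
      encounter_setting = if (m["enc_type"] %in% names(raw))
        .enc_setting(trimws(raw[[m["enc_type"]]]), colmap) else "other"
    )
    bad <- is.na(dt$patient_id) | is.na(dt$encounter_date)
    note("encounter", "bad_date_or_id", sum(bad))
    out$encounter <- dt[!bad]
  }

  read_dx <- function(path, table) {
    m <- colmap$diagnosis
    raw <- read_raw(path)
    .require_cols(raw, m[c("patient_id", "dx_date", "code")], table, path)
    dt <- data.table(
      patient_id = raw[[m["patient_id"]]],
      dx_date = .parse_date(raw[[m["dx_date"]]]),
      code = trimws(raw[[m["code"]]]),
      code_type_raw = if (m["code_type"] %in% names(raw)) trimws(raw[[m["code_type"]]]) else NA_character_,
      source_raw = if (m["source"] %in% names(raw)) trimws(raw[[m["source"]]]) else NA_character_
    )
    dt[, code_type := unname(colmap$dx_type_map[code_type_raw])]
    dt[, source := unname(colmap$source_map[source_raw])]
    # also accept already-normalized source labels (round-trip of our own output)
    already <- dt$source_raw %in% c("provider", "billing", "claims")
    dt[already, source := source_raw]
    bad_date <- is.na(dt$dx_date) | is.na(dt$patient_id)
    bad_code <- !bad_date & (is.na(dt$code) | dt$code == "")
    bad_type <- !bad_date & !bad_code & is.na(dt$code_type)
    bad_src  <- !bad_date & !bad_code & !bad_type & is.na(dt$source)
    note(table, "bad_date_or_id", sum(bad_date))
    note(table, "empty_code", sum(bad_code))
    note(table, "unknown_code_type", sum(bad_type))
    note(table, "unmapped_source", sum(bad_src))
    dt <- dt[!(bad_date | bad_code | bad_type | bad_src),
             .(patient_id, dx_date, code, code_type, source)]
    dt
  }
  dx_parts <- list()
  if (!is.null(paths$diagnosis)) dx_parts$diagnosis <- read_dx(paths$diagnosis, "diagnosis")
  if (!is.null(paths$condition)) dx_parts$condition <- read_dx(paths$condition, "condition")
  if (length(dx_parts)) out$diagnosis <- data.table::rbindlist(dx_parts)

  if (!is.null(paths$vital)) {
    m <- colmap$vital
    raw <- read_raw(paths$vital)
    .require_cols(raw, m[c("patient_id", "measure_date")], "vital", paths$vital)
    num <- function(col) if (m[col] %in% names(raw)) suppressWarnings(as.numeric(raw[[m[col]]])) else NA_real_
    dt <- data.table(
      patient_id = raw[[m["patient_id"]]],
      measure_date = .parse_date(raw[[m["measure_date"]]]),
      systolic = num("systolic"),
      diastolic = num("diastolic"),
      encounter_setting = if (m["enc_type"] %in% names(raw))
        .enc_setting(trimws(raw[[m["enc_type"]]]), colmap) else "other"
    )
    bad <- is.na(dt$patient_id) | is.na(dt$measure_date)
    note("vital", "bad_date_or_id", sum(bad))
    dt <- dt[!bad]
    # sanity bounds: 0 < mmHg < 400; out-of-range readings are suspect rows
    for (col in c("systolic", "diastolic")) {
      v <- dt[[col]]
      bad_v <- !is.na(v) & (v <= 0 | v >= 400)
      note("vital", paste0("out_of_range_", col), sum(bad_v))
      data.table::set(dt, i = which(bad_v), j = col, value = NA_real_)
    }
    none <- is.na(dt$systolic) & is.na(dt$diastolic)
    note("vital", "no_numeric_reading", sum(none))
    out$vital <- dt[!none]
  }

  if (!is.null(paths$lab_result)) {
    m <- colmap$lab_result
    raw <- read_raw(paths$lab_result)
    .require_cols(raw, m[c("patient_id", "specimen_date", "code")], "lab_result", paths$lab_result)
    dt <- data.table(
      patient_id = raw[[m["patient_id"]]],
      specimen_date = .parse_date(raw[[m["specimen_date"]]]),
      code = trimws(raw[[m["code"]]]),
      value = suppressWarnings(as.numeric(raw[[m["value"]]]))
    )
    bad <- is.na(dt$patient_id) | is.na(dt$specimen_date)
    note("lab_result", "bad_date_or_id", sum(bad))
    badv <- !bad & (is.na(dt$value) | !is.finite(dt$value) | dt$value < 0)
    note("lab_result", "bad_value", sum(badv))
    out$lab_result <- dt[!(bad | badv)]
  }

  for (tb in c("demographic", "encounter", "diagnosis", "vital", "lab_result")) {
    if (nrow(out[[tb]]) == 0 && !is.null(paths[[tb]])) {
      warning("table '", tb, "' loaded empty", call. = FALSE)
    }
    if (verbose) message(sprintf("read %-11s %8d rows", tb, nrow(out[[tb]])))
  }
  data.table::setattr(out, "load_report", report)
  data.table::setattr(out, "class", c("cdm_tables", "list"))
  out
}

#' Empty typed CDM tables
#' @return A `cdm_tables` list with zero-row tables of the canonical schema.
#' @export
empty_cdm_tables <- function() {
  out <- list(
    demographic = data.table(patient_id = character(), birth_date = as.Date(character()),
                             sex = character()),
    encounter = data.table(patient_id = character(), encounter_date = as.Date(character()),
                           encounter_setting = character()),
    diagnosis = data.table(patient_id = character(), dx_date = as.Date(character()),
                           code = character(), code_type = character(), source = character()),
    vital = data.table(patient_id = character(), measure_date = as.Date(character()),
                       systolic = numeric(), diastolic = numeric(),
                       encounter_setting = character()),
    lab_result = data.table(patient_id = character(), specimen_date = as.Date(character()),
                            code = character(), value = numeric())
  )
  structure(out, class = c("cdm_tables", "list"))
}

#' Write CDM-shaped tables
#'
#' Writes one CSV per table in the CDM dialect [read_cdm_tables()] consumes
#' (CDM column names, `OD`/`BI`/`CL` sources, `09`/`10` code types, ISO-8601
#' dates), so that `read_cdm_tables(write_cdm_tables(x))` round-trips.
#'
#' @param tables A `cdm_tables` list (from [read_cdm_tables()] or
#'   [synth_generate()]).
#' @param dir Output directory (created if needed).
#' @param colmap Column map from [cdm_colmap()].
#' @return Invisibly, a named vector of file paths.
#' @export
write_cdm_tables <- function(tables, dir, colmap = cdm_colmap()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!dir.exists(dir)) stop("unwritable directory: ", dir, call. = FALSE)
  inv_source <- setNames(names(colmap$source_map), unname(colmap$source_map))
  inv_type <- c(ICD9CM = "09", ICD10CM = "10")
  setting_code <- c(outpatient = colmap$outpatient_codes[1],
                    inpatient = colmap$inpatient_codes[1],
                    emergency = colmap$emergency_codes[1], other = "OT")
  paths <- c()
  wr <- function(dt, name) {
    p <- file.path(dir, paste0(name, ".csv"))
    data.table::fwrite(dt, p, dateTimeAs = "ISO")
    paths[name] <<- p
  }
  m <- colmap$demographic
  wr(setNames(tables$demographic[, .(patient_id, birth_date, sex)],
              unname(m[c("patient_id", "birth_date", "sex")])), "demographic")
  m <- colmap$encounter
  wr(setNames(tables$encounter[, .(patient_id, encounter_date,
                                   unname(setting_code[encounter_setting]))],
              unname(m[c("patient_id", "encounter_date", "enc_type")])), "encounter")
  m <- colmap$diagnosis
  wr(setNames(tables$diagnosis[, .(patient_id, dx_date, code,
                                   unname(inv_type[code_type]),
                                   unname(inv_source[source]))],
              unname(m[c("patient_id", "dx_date", "code", "code_type", "source")])),
     "diagnosis")
  m <- colmap$vital
  wr(setNames(tables$vital[, .(patient_id, measure_date, systolic, diastolic,
                               unname(setting_code[encounter_setting]))],
              unname(m[c("patient_id", "measure_date", "systolic", "diastolic",
                         "enc_type")])), "vital")
  m <- colmap$lab_result
  wr(setNames(tables$lab_result[, .(patient_id, specimen_date, code, value)],
              unname(m[c("patient_id", "specimen_date", "code", "value")])),
     "lab_result")
  invisible(paths)
}

#' Filter a dated record table to the study window
#'
#' Measurement-kind records are kept iff
#' `data_start <= date <= measurement_cutoff`; diagnosis-kind records
#' (diagnoses and encounters) iff `data_start <= date <= diagnosis_cutoff`.
#' Both boundaries are inclusive. Order-preserving and idempotent.
#'
#' @param dt A data.table with a `Date` column (the first `Date`-classed
#'   column is used, or pass `date_col`).
#' @param window A [study_window()].
#' @param kind `"measurement"` or `"diagnosis"`.
#' @param date_col Optional explicit date column name.
#' @return The filtered data.table (a copy).
#' @export
filter_window <- function(dt, window, kind = c("measurement", "diagnosis"),
                          date_col = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(window, "study_window"))
  if (is.null(date_col)) {
    is_date <- vapply(dt, function(col) inherits(col, "Date"), logical(1))
    if (!any(is_date)) stop("no Date column found", call. = FALSE)
    date_col <- names(dt)[which(is_date)[1]]
  }
  hi <- if (kind == "measurement") window$measurement_cutoff else window$diagnosis_cutoff
  d <- dt[[date_col]]
  dt[!is.na(d) & d >= window$data_start & d <= hi]
}

#' @export
print.study_window <- function(x, ...) {
  cat(sprintf("study window: data from %s, measurements through %s, diagnoses through %s\n",
              x$data_start, x$measurement_cutoff, x$diagnosis_cutoff))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
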