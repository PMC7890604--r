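## Structured-diagnosis identification: ICD-9-CM / ICD-10-CM parent-prefix
## matching and the first structured diagnosis per patient-condition, with
## provider > billing > claims precedence on same-date ties.

#' Default ICD parent code groups per condition
#'
#' Parent prefixes are either 3 characters (a whole ICD family, e.g. `401`,
#' `I10`) or 5 characters with a dot at position 4 (a dotted subcategory,
#' e.g. `272.0`, `E78.5`). A code matches a condition iff its first 3 or
#' first 5 characters equal a parent prefix of the matching code system.
#' Defaults:
#' \describe{
#'   \item{HTN}{ICD-9 401, 402, 403, 404, 405, 642; ICD-10 I10, I11, I12,
#'     I13, I15, I16, I27, O13. (I27, pulmonary hypertension, and the
#'     pregnancy groups 642/O13 are part of the shipped set; edit the table
#'     to change study scope.)}
#'   \item{DM}{ICD-9 249, 250; ICD-10 E08, E09, E10, E11, E13.}
#'   \item{HLD}{ICD-9 272.0, 272.2, 272.3, 272.4, 272.9; ICD-10 E78.0,
#'     E78.2, E78.3, E78.4, E78.5, E78.7, E78.8, E78.9.}
#' }
#' @return Nested list: `groups[[condition]][[code_type]]` -> character
#'   vector of parent prefixes.
#' @export
code_groups <- function() {
  g <- list(
    HTN = list(ICD9CM = c("401", "402", "403", "404", "405", "642"),
               ICD10CM = c("I10", "I11", "I12", "I13", "I15", "I16", "I27", "O13")),
    DM = list(ICD9CM = c("249", "250"),
              ICD10CM = c("E08", "E09", "E10", "E11", "E13")),
    HLD = list(ICD9CM = c("272.0", "272.2", "272.3", "272.4", "272.9"),
               ICD10CM = c("E78.0", "E78.2", "E78.3", "E78.4", "E78.5",
                           "E78.7", "E78.8", "E78.9"))
  )
  for (cond in names(g)) for (ct in names(g[[cond]])) {
    p <- g[[cond]][[ct]]
    stopifnot(all(nchar(p) == 3L | (nchar(p) == 5L & substr(p, 4, 4) == ".")))
  }
  g
}

#' Normalize an ICD code string
#'
#' Uppercases, strips whitespace, and repairs the dotless dialect: a string
#' of 4+ characters with no dot gets a dot inserted after character 3
#' (`"E780"` -> `"E78.0"`, `"40110"` -> `"401.10"`). Already-dotted or
#' 3-character codes are returned unchanged. Vectorized.
#'
#' @param code Character vector of raw code strings.
#' @return Character vector of normalized codes; empty-after-stripping
#'   inputs become `NA` (callers drop and count them).
#' @export
normalize_code <- function(code) {
  x <- toupper(trimws(code))
  x[!nzchar(x) | is.na(x)] <- NA_character_
  fix <- !is.na(x) & nchar(x) >= 4L & !grepl(".", x, fixed = TRUE)
  x[fix] <- paste0(substr(x[fix], 1, 3), ".", substring(x[fix], 4))
  x
}

#' Match normalized codes against a condition's parent groups
#'
#' TRUE iff the first 3 characters equal a 3-character parent or the first
#' 5 characters equal a 5-character parent, within the matching code system.
#' Codes never match across code systems. Vectorized over `code` (and
#' `code_type` if the same length).
#'
#' @param code Normalized code strings (see [normalize_code()]).
#' @param code_type `"ICD9CM"` or `"ICD10CM"` (scalar or vector).
#' @param condition `"HTN"`, `"HLD"`, or `"DM"`.
#' @param groups Code group table from [code_groups()].
#' @return Logical vector; unknown code types yield `FALSE`.
#' @export
match_code <- function(code, code_type, condition, groups = code_groups()) {
  stopifnot(condition %in% names(groups))
  g <- groups[[condition]]
  if (length(code_type) == 1L) code_type <- rep(code_type, length(code))
  stopifnot(length(code_type) == length(code))
  out <- logical(length(code))
  for (ct in names(g)) {
    sel <- !is.na(code) & code_type == ct
    if (!any(sel)) next
    p3 <- g[[ct]][nchar(g[[ct]]) == 3L]
    p5 <- g[[ct]][nchar(g[[ct]]) == 5L]
    out[sel] <- (substr(code[sel], 1, 3) %in% p3) |
                (substr(code[sel], 1, 5) %in% p5)
  }
  out
}

.SOURCE_PRECEDENCE <- c(provider = 1L, billing = 2L, claims = 3L)

#' First structured diagnosis per patient for a condition
#'
#' Among diagnosis records matching the condition's code groups (after
#' [normalize_code()]), returns the earliest `dx_date` per patient; ties on
#' that date are broken by source precedence provider > billing > claims.
#' Precedence only ever applies within a single date: the returned date is
#' the global minimum matching date. Invariant to input row order.
#'
#' @param dx Diagnosis record table (`patient_id`, `dx_date`, `code`,
#'   `code_type`, `source`), already filtered to the diagnosis window.
#' @param condition Condition name.
#' @param groups Code group table from [code_groups()].
#' @return data.table (`patient_id`, `condition`, `first_dx_date`,
#'   `dx_source`), one row per patient with any matching record.
#' @export
first_structured_dx <- function(dx, condition, groups = code_groups()) {
  empty <- data.table(patient_id = character(), condition = character(),
                      first_dx_date = as.Date(character()), dx_source = character())
  if (nrow(dx) == 0) return(empty)
  d <- dx[, .(patient_id, dx_date, code = normalize_code(code), code_type, source)]
  d <- d[!is.na(code)]
  d <- d[match_code(code, code_type, condition, groups)]
  if (nrow(d) == 0) return(empty)
  d[, src_rank := .SOURCE_PRECEDENCE[source]]
  data.table::setorder(d, patient_id, dx_date, src_rank)
  out <- d[, .(condition = condition, first_dx_date = dx_date[1L],
               dx_source = source[1L]), by = patient_id]
  data.table::setkey(out, patient_id)
  out[]
}
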