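# Independent oracles and small fixture builders shared across test files.

# Brute-force two-signal rule: enumerate all ordered pairs (d', d) with
# d' < d; a pair qualifies iff d - d' >= sep. Returns NULL or the
# first/second signal dates (first = series minimum, second = minimum d over
# qualifying pairs).
bf_signal_pair <- function(dates, sep) {
  dates <- sort(unique(dates))
  if (length(dates) < 2) return(NULL)
  qual_d <- c()
  for (a in seq_along(dates)) for (b in seq_along(dates)) {
    if (a < b && as.integer(dates[b] - dates[a]) >= sep) qual_d <- c(qual_d, dates[b])
  }
  if (is.null(qual_d)) return(NULL)
  list(first = min(dates), second = min(qual_d))
}

# Regex-based ICD prefix oracle, with its own dotless repair via sub():
# a code matches iff the anchored literal parent prefix matches at a 3- or
# 5-character boundary of the repaired, uppercased string.
oracle_match <- function(raw, code_type, condition, groups = code_groups()) {
  x <- toupper(gsub("^\\s+|\\s+$", "", raw))
  if (!nzchar(x)) return(FALSE)
  if (nchar(x) >= 4 && !grepl("\\.", x)) x <- sub("^(.{3})", "\\1.", x)
  parents <- groups[[condition]][[code_type]]
  if (is.null(parents)) return(FALSE)
  any(vapply(parents, function(p) {
    n <- nchar(p)
    nchar(x) >= n && grepl(paste0("^", gsub("\\.", "\\\\.", p)),
                           substr(x, 1, n))
  }, logical(1)))
}

# Random ICD-like code strings: a mix of true children of the shipped
# parents, near-misses, and noise, in dotted and dotless dialects.
random_icd_like <- function(n, rng_parents) {
  kinds <- sample(1:3, n, replace = TRUE)
  out <- character(n)
  for (i in seq_len(n)) {
    if (kinds[i] == 1) {                      # child of a real parent
      p <- sample(rng_parents, 1)
      suffix <- sample(c("", ".0", ".9", ".01", "0", "1", "9", "00"), 1)
      out[i] <- paste0(p, suffix)
    } else if (kinds[i] == 2) {               # structured near-miss
      out[i] <- paste0(sample(c(LETTERS, ""), 1),
                       paste(sample(0:9, sample(2:3, 1), replace = TRUE), collapse = ""),
                       sample(c("", ".", ".1", ".23"), 1))
    } else {                                  # noise
      out[i] <- paste(sample(c(LETTERS, 0:9, "."), sample(1:7, 1), replace = TRUE),
                      collapse = "")
    }
  }
  # random whitespace and case
  pad <- sample(c("", " ", "  "), n, replace = TRUE)
  ifelse(runif(n) < 0.3, tolower(paste0(pad, out, pad)), paste0(pad, out, pad))
}

# A hand-built 3-patient CDM world for DM: one pre-existing, one eventual at
# 100 days, one never (censored at 366 days).
fixture_three_patients <- function() {
  tabs <- empty_cdm_tables()
  d <- as.Date
  lab <- function(pid, dates) data.table::data.table(
    patient_id = pid, specimen_date = d(dates), code = "4548-4", value = 7.0)
  tabs$lab_result <- data.table::rbindlist(list(
    lab("A", c("2015-01-01", "2015-02-15")),
    lab("B", c("2015-01-01", "2015-03-01")),
    lab("C", c("2015-01-01", "2015-03-01"))))
  tabs$diagnosis <- data.table::data.table(
    patient_id = c("A", "B"),
    dx_date = d(c("2014-06-01", "2015-06-09")),   # B: second signal + 100d
    code = c("E11.9", "250.00"),
    code_type = c("ICD10CM", "ICD9CM"),
    source = c("provider", "billing"))
  tabs$encounter <- data.table::data.table(
    patient_id = c("A", "B", "C"),
    encounter_date = d(c("2016-01-01", "2016-01-01", "2016-03-01")),
    encounter_setting = "outpatient")
  tabs$demographic <- data.table::data.table(
    patient_id = c("A", "B", "C"), birth_date = d("1960-01-01"), sex = "F")
  tabs
}
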