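## Seeded synthetic PCORnet-CDM-shaped extracts with a ground-truth ledger.
##
## The generator states a world: encounters are a homogeneous Poisson
## process over [data_start, diagnosis_cutoff]; measurements attach only to
## encounters on or before measurement_cutoff (blood pressure at outpatient
## encounters, labs at any setting), so every subject's most recent
## encounter is well-defined and censoring times extend through the
## diagnosis window, as in the real asymmetric-cutoff design. Diseased
## patients produce above-threshold values with probability p_abnormal per
## measurement; healthy patients exceed the threshold at a small false-
## positive rate (default 2%) so the 30-day pairing rule's specificity is
## exercised. Structured diagnoses are placed relative to the REALIZED
## signal dates (pre-existing before the first signal; early between the
## signals; eventual at second signal + drawn delay; never absent). A drawn
## delay landing past diagnosis_cutoff emits no record -- the subject is
## censored, as in real data -- and is flagged as a degenerate draw in the
## truth ledger, as are diseased patients whose measurement draws never form
## a qualifying pair and healthy patients whose false signals do.

#' Per-condition synthetic-model parameters
#'
#' @param name Condition (`"HTN"`, `"HLD"`, `"DM"`).
#' @param prevalence Latent disease probability per patient.
#' @param p_measure Probability a measurement is taken at an eligible
#'   encounter (outpatient for blood pressure; any setting for labs).
#' @param p_abnormal P(above threshold) per measurement when diseased.
#' @param p_exceed P(above threshold) per measurement when healthy
#'   (false-positive exceedance, default 0.02).
#' @param noise_scale Half-normal spread of values around the threshold, in
#'   assay units (mmHg, mg/dL, or %).
#' @param p_pre_existing,p_early,p_never Latent diagnosis-model
#'   probabilities: structured dx before the first signal / between the
#'   signals / absent. The remainder is "eventual": recorded at the second
#'   signal plus a drawn delay.
#' @param delay_dist `"exponential"` or `"lognormal"`.
#' @param delay_mean Mean recording delay in days (exponential).
#' @param delay_meanlog,delay_sdlog Lognormal parameters (used when
#'   `delay_dist = "lognormal"`).
#' @param source_mix Named probabilities over provider/billing/claims for
#'   the first structured diagnosis source; must sum to 1.
#' @return A `synth_condition` list.
#' @export
synth_condition <- function(name = c("HTN", "HLD", "DM"),
                            prevalence = NULL, p_measure = NULL,
                            p_abnormal = 0.9, p_exceed = 0.02,
                            noise_scale = NULL,
                            p_pre_existing = NULL, p_early = NULL, p_never = NULL,
                            delay_dist = c("exponential", "lognormal"),
                            delay_mean = NULL, delay_meanlog = 5, delay_sdlog = 1,
                            source_mix = c(provider = 0.65, billing = 0.30,
                                           claims = 0.05)) {
  name <- match.arg(name)
  delay_dist <- match.arg(delay_dist)
  # defaults anchored loosely to the reported world: HTN most prevalent,
  # most often pre-existing/never; DM almost always eventually coded
  def <- switch(name,
    HTN = list(prevalence = 0.25, p_measure = 0.85, noise_scale = 12,
               p_pre_existing = 0.40, p_early = 0.15, p_never = 0.30,
               delay_mean = 400),
    HLD = list(prevalence = 0.15, p_measure = 0.15, noise_scale = 25,
               p_pre_existing = 0.37, p_early = 0.20, p_never = 0.15,
               delay_mean = 200),
    DM  = list(prevalence = 0.10, p_measure = 0.12, noise_scale = 0.8,
               p_pre_existing = 0.55, p_early = 0.30, p_never = 0.04,
               delay_mean = 170)
  )
  p <- list(name = name,
            prevalence = prevalence %||% def$prevalence,
            p_measure = p_measure %||% def$p_measure,
            p_abnormal = p_abnormal, p_exceed = p_exceed,
            noise_scale = noise_scale %||% def$noise_scale,
            p_pre_existing = p_pre_existing %||% def$p_pre_existing,
            p_early = p_early %||% def$p_early,
            p_never = p_never %||% def$p_never,
            delay_dist = delay_dist,
            delay_mean = delay_mean %||% def$delay_mean,
            delay_meanlog = delay_meanlog, delay_sdlog = delay_sdlog,
            source_mix = source_mix)
  probs <- c(p$prevalence, p$p_measure, p$p_abnormal, p$p_exceed,
             p$p_pre_existing, p$p_early, p$p_never)
  stopifnot(all(probs >= 0 & probs <= 1),
            p$p_pre_existing + p$p_early + p$p_never <= 1,
            p$noise_scale > 0, p$delay_mean > 0,
            setequal(names(source_mix), c("provider", "billing", "claims")),
            abs(sum(source_mix) - 1) < 1e-8)
  structure(p, class = "synth_condition")
}

#' Synthetic study configuration
#'
#' @param n_patients Number of patients.
#' @param seed Integer master seed; per-patient substreams are derived
#'   deterministically from it, so generation is reproducible and patient
#'   subsets are stable.
#' @param window A [study_window()].
#' @param encounter_rate Mean encounters per patient-year (Poisson).
#' @param enc_setting_probs Named probabilities over encounter settings.
#' @param conditions Named list of [synth_condition()] objects.
#' @param dotless_frac Fraction of emitted diagnosis codes written in the
#'   dotless ICD dialect (exercises code normalization downstream).
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_patients = 1000L, seed = 20120101L,
                         window = study_window(),
                         encounter_rate = 6,
                         enc_setting_probs = c(outpatient = 0.78, inpatient = 0.10,
                                               emergency = 0.07, other = 0.05),
                         conditions = NULL,
                         dotless_frac = 0.2) {
  if (is.null(conditions)) {
    conditions <- setNames(lapply(dxdelay::conditions(), synth_condition),
                           dxdelay::conditions())
  }
  cfg <- list(n_patients = as.integer(n_patients), seed = as.integer(seed),
              window = window, encounter_rate = encounter_rate,
              enc_setting_probs = enc_setting_probs,
              conditions = conditions, dotless_frac = dotless_frac)
  stopifnot(cfg$n_patients >= 1, inherits(window, "study_window"),
            encounter_rate > 0,
            abs(sum(enc_setting_probs) - 1) < 1e-8,
            dotless_frac >= 0, dotless_frac <= 1)
  meas_span <- as.integer(window$measurement_cutoff - window$data_start)
  min_sep <- 30L
  if (meas_span < min_sep + 1L) {
    stop("infeasible config: measurement window of ", meas_span,
         " days is too short for any ", min_sep, "-day signal pair", call. = FALSE)
  }
  structure(cfg, class = "synth_config")
}

.pat_seed <- function(seed, i) {
  as.integer((as.double(seed) %% 1000003 + 1) * 1009 + i) %% 2147483629L
}

.THRESHOLDS <- list(HTN = c(sys = 140, dia = 90), HLD = 130, DM = 6.5)

## values strictly respect the abnormal flag after rounding
.draw_values <- function(cond, abnormal, noise) {
  n <- length(abnormal)
  if (cond == "HTN") {
    sys <- ifelse(abnormal, 140 + abs(rnorm(n, 0, noise)),
                  pmax(90, 139 - abs(rnorm(n, 0, noise))))
    dia <- ifelse(abnormal, 90 + abs(rnorm(n, 0, noise / 2)),
                  pmax(55, 89 - abs(rnorm(n, 0, noise / 2))))
    list(systolic = round(sys), diastolic = round(dia))
  } else if (cond == "HLD") {
    round(ifelse(abnormal, 130 + abs(rnorm(n, 0, noise)),
                 pmax(40, 129 - abs(rnorm(n, 0, noise)))))
  } else {
    round(ifelse(abnormal, 6.5 + abs(rnorm(n, 0, noise)),
                 pmax(4.5, 6.4 - abs(rnorm(n, 0, noise)))), 1)
  }
}

.ICD10_SWITCH <- as.Date("2015-10-01")

.draw_code <- function(cond, dx_date, dotless_frac, groups) {
  ct <- if (dx_date < .ICD10_SWITCH) "ICD9CM" else "ICD10CM"
  parents <- groups[[cond]][[ct]]
  parent <- sample(parents, 1L)
  code <- if (nchar(parent) == 3L) {
    if (runif(1) < 0.5) paste0(parent, ".", sample(0:99, 1L)) else parent
  } else {
    if (runif(1) < 0.5) paste0(parent, sample(0:9, 1L)) else parent
  }
  if (runif(1) < dotless_frac) code <- sub(".", "", code, fixed = TRUE)
  list(code = code, code_type = ct)
}

## realized first/second signal dates from per-day signal flags
.signal_pair <- function(dates, min_sep = 30L) {
  if (length(dates) == 0) return(NULL)
  first <- min(dates)
  qual <- dates[as.integer(dates - first) >= min_sep & dates > first]
  if (!length(qual)) return(NULL)
  list(first = first, second = min(qual))
}

#' Generate a synthetic CDM extract with ground truth
#'
#' Deterministic given the config seed: two runs with the same config yield
#' identical tables and ledger. See the module header and the methods
#' vignette for the generative model.
#'
#' The truth ledger has one row per patient-condition that is latently
#' diseased or that realizes a false computed diagnosis, with columns:
#' `patient_id`, `condition`, `diseased`, `first_signal_date`,
#' `second_signal_date` (realized; NA if no qualifying pair),
#' `category_intended` (latent assignment), `category_expected` (what the
#' pipeline should observe; `"absent"` when no computed diagnosis arises),
#' `dx_date`, `dx_source`, `delay_drawn`, `degenerate`, `reason`.
#'
#' @param config A [synth_config()].
#' @return List with `tables` (a `cdm_tables` list), `truth` (the ledger
#'   data.table), and `config`.
#' @export
synth_generate <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  w <- config$window
  span_all <- as.integer(w$diagnosis_cutoff - w$data_start)
  years_all <- span_all / 365.25
  groups <- code_groups()
  settings <- names(config$enc_setting_probs)

  n <- config$n_patients
  # accumulate plain column lists; one rbindlist per table at the end
  acc <- list(enc = vector("list", n), vit = vector("list", 2L * n),
              lab = vector("list", 2L * n), dx = vector("list", 3L * n),
              truth = vector("list", 3L * n), demo = vector("list", n))
  ix <- list(vit = 0L, lab = 0L, dx = 0L, truth = 0L)
  push <- function(tab, row) {
    ix[[tab]] <<- ix[[tab]] + 1L
    if (ix[[tab]] > length(acc[[tab]])) length(acc[[tab]]) <<- 2L * ix[[tab]]
    acc[[tab]][[ix[[tab]]]] <<- row
  }

  for (i in seq_len(n)) {
    set.seed(.pat_seed(config$seed, i))
    pid <- sprintf("P%06d", i)

    n_enc <- rpois(1, config$encounter_rate * years_all)
    if (n_enc == 0) {
      acc$demo[[i]] <- list(patient_id = pid,
                            birth_date = w$data_start - sample(7000:30000, 1L),
                            sex = sample(c("F", "M"), 1L))
      next
    }
    enc_date <- sort(w$data_start + sample.int(span_all + 1L, n_enc, replace = TRUE) - 1L)
    enc_set <- sample(settings, n_enc, replace = TRUE, prob = config$enc_setting_probs)
    acc$demo[[i]] <- list(patient_id = pid,
                          birth_date = w$data_start - sample(7000:30000, 1L),
                          sex = sample(c("F", "M"), 1L))
    acc$enc[[i]] <- list(patient_id = rep(pid, n_enc), encounter_date = enc_date,
                         encounter_setting = enc_set)
    in_meas <- enc_date <= w$measurement_cutoff

    for (cond in names(config$conditions)) {
      p <- config$conditions[[cond]]
      diseased <- runif(1) < p$prevalence
      p_hit <- if (diseased) p$p_abnormal else p$p_exceed

      if (cond == "HTN") {
        elig <- which(in_meas & enc_set == "outpatient")
      } else {
        elig <- which(in_meas)
      }
      take <- elig[runif(length(elig)) < p$p_measure]
      m_dates <- enc_date[take]
      abnormal <- runif(length(take)) < p_hit

      if (length(take)) {
        if (cond == "HTN") {
          v <- .draw_values("HTN", abnormal, p$noise_scale)
          push("vit", list(patient_id = rep(pid, length(take)),
                           measure_date = m_dates,
                           systolic = v$systolic, diastolic = v$diastolic,
                           encounter_setting = enc_set[take]))
          # a few inpatient readings: must be ignored by the outpatient-only rule
          inp <- which(in_meas & enc_set == "inpatient")
          inp <- inp[runif(length(inp)) < p$p_measure]
          if (length(inp)) {
            vi <- .draw_values("HTN", runif(length(inp)) < p_hit, p$noise_scale)
            push("vit", list(patient_id = rep(pid, length(inp)),
                             measure_date = enc_date[inp],
                             systolic = vi$systolic, diastolic = vi$diastolic,
                             encounter_setting = enc_set[inp]))
          }
        } else {
          val <- .draw_values(cond, abnormal, p$noise_scale)
          code <- if (cond == "HLD") sample(c("13457-7", "18262-6"), length(take),
                                            replace = TRUE) else rep("4548-4", length(take))
          push("lab", list(patient_id = rep(pid, length(take)),
                           specimen_date = m_dates, code = code, value = val))
        }
      }

      # realized per-day signals: a day signals iff every draw that day is
      # abnormal (the pipeline takes the daily minimum)
      if (length(take)) {
        day_ok <- tapply(abnormal, as.integer(m_dates), all)
        sig_days <- as.Date(as.integer(names(day_ok))[day_ok], origin = "1970-01-01")
      } else sig_days <- as.Date(integer(), origin = "1970-01-01")
      pair <- .signal_pair(sig_days, 30L)

      if (is.null(pair)) {
        if (diseased) {
          push("truth", list(
            patient_id = pid, condition = cond, diseased = TRUE,
            first_signal_date = as.Date(NA), second_signal_date = as.Date(NA),
            category_intended = NA_character_, category_expected = "absent",
            dx_date = as.Date(NA), dx_source = NA_character_,
            delay_drawn = NA_real_, degenerate = TRUE, reason = "no_signal_pair"))
        }
        next
      }

      if (!diseased) {
        # healthy false-positive exceedances formed a qualifying pair: the
        # pipeline will compute a diagnosis; no structured dx is placed
        push("truth", list(
          patient_id = pid, condition = cond, diseased = FALSE,
          first_signal_date = pair$first, second_signal_date = pair$second,
          category_intended = NA_character_, category_expected = "never",
          dx_date = as.Date(NA), dx_source = NA_character_,
          delay_drawn = NA_real_, degenerate = TRUE, reason = "false_signal_pair"))
        next
      }

      u <- runif(1)
      cat_int <- if (u < p$p_pre_existing) "pre_existing"
        else if (u < p$p_pre_existing + p$p_early) "early"
        else if (u < p$p_pre_existing + p$p_early + p$p_never) "never"
        else "eventual"
      dx_date <- as.Date(NA); src <- NA_character_; delay <- NA_real_
      cat_exp <- cat_int; degen <- FALSE; reason <- NA_character_

      if (cat_int == "pre_existing") {
        gap <- as.integer(pair$first - w$data_start)
        if (gap >= 1L) {
          dx_date <- w$data_start + sample.int(gap, 1L) - 1L   # in [start, first-1]
        } else {
          degen <- TRUE; reason <- "pre_dx_unplaceable"; cat_exp <- "never"
        }
      } else if (cat_int == "early") {
        gap <- as.integer(pair$second - pair$first)            # >= 30
        dx_date <- pair$first + sample.int(gap, 1L) - 1L       # in [first, second-1]
      } else if (cat_int == "eventual") {
        delay <- if (p$delay_dist == "exponential") rexp(1, 1 / p$delay_mean)
                 else rlnorm(1, p$delay_meanlog, p$delay_sdlog)
        delay <- round(delay)
        if (pair$second + delay <= w$diagnosis_cutoff) {
          dx_date <- pair$second + delay
        } else {
          degen <- TRUE; reason <- "delay_clipped"; cat_exp <- "never"
        }
      }

      if (!is.na(dx_date)) {
        src <- sample(names(p$source_mix), 1L, prob = p$source_mix)
        cd <- .draw_code(cond, dx_date, config$dotless_frac, groups)
        push("dx", list(patient_id = pid, dx_date = dx_date,
                        code = cd$code, code_type = cd$code_type,
                        source = src))
      }
      push("truth", list(
        patient_id = pid, condition = cond, diseased = TRUE,
        first_signal_date = pair$first, second_signal_date = pair$second,
        category_intended = cat_int, category_expected = cat_exp,
        dx_date = dx_date, dx_source = src, delay_drawn = delay,
        degenerate = degen, reason = reason))
    }
  }

  tables <- empty_cdm_tables()
  bind <- function(lst, empty) {
    keep <- lst[!vapply(lst, is.null, logical(1))]
    if (!length(keep)) return(empty)
    data.table::rbindlist(c(list(empty), keep), use.names = TRUE)
  }
  tables$demographic <- bind(acc$demo, tables$demographic)
  tables$encounter <- bind(acc$enc, tables$encounter)
  tables$vital <- bind(acc$vit, tables$vital)
  tables$lab_result <- bind(acc$lab, tables$lab_result)
  tables$diagnosis <- bind(acc$dx, tables$diagnosis)
  truth_empty <- data.table(
    patient_id = character(), condition = character(), diseased = logical(),
    first_signal_date = as.Date(character()), second_signal_date = as.Date(character()),
    category_intended = character(), category_expected = character(),
    dx_date = as.Date(character()), dx_source = character(),
    delay_drawn = numeric(), degenerate = logical(), reason = character())
  truth <- bind(acc$truth, truth_empty)
  list(tables = tables, truth = truth, config = config)
}

#' Summarize a truth ledger
#'
#' @param truth Truth ledger from [synth_generate()].
#' @return List with `n_subjects` (ledger rows), `counts` (rows per
#'   condition and expected category), and `degenerate` (rows per condition
#'   and degeneracy reason).
#' @export
truth_report <- function(truth) {
  if (nrow(truth) == 0) {
    return(list(n_subjects = 0L,
                counts = data.table(condition = character(),
                                    category_expected = character(), n = integer()),
                degenerate = data.table(condition = character(),
                                        reason = character(), n = integer())))
  }
  list(
    n_subjects = nrow(truth),
    counts = truth[, .(n = .N), keyby = .(condition, category_expected)],
    degenerate = truth[degenerate == TRUE, .(n = .N), keyby = .(condition, reason)]
  )
}

#' Write a synthetic extract and its truth ledger to disk
#'
#' @param gen Output of [synth_generate()].
#' @param dir Output directory.
#' @return Invisibly, the file paths.
#' @export
synth_write <- function(gen, dir) {
  paths <- write_cdm_tables(gen$tables, dir)
  tp <- file.path(dir, "truth.csv")
  data.table::fwrite(gen$truth, tp, dateTimeAs = "ISO")
  rep <- truth_report(gen$truth)
  jp <- file.path(dir, "truth_summary.json")
  jsonlite::write_json(list(n_subjects = rep$n_subjects, counts = rep$counts,
                            degenerate = rep$degenerate),
                       jp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, truth = tp, truth_summary = jp))
}
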