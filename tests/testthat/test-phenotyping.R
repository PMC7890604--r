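specs <- default_condition_specs()
D <- function(x) as.Date(x, origin = "1970-01-01")

test_that("aggregate_daily takes independent same-day minima and outpatient-only BP", {
  vit <- data.table::data.table(
    patient_id = "p1",
    measure_date = as.Date("2015-01-01"),
    systolic = c(150, 135), diastolic = c(85, 95),
    encounter_setting = "outpatient")
  daily <- aggregate_daily(vit, NULL, specs$HTN)
  expect_equal(daily$min_systolic, 135)
  expect_equal(daily$min_diastolic, 85)
  expect_equal(nrow(detect_signals(daily, specs$HTN)), 0)  # (135, 85) is not a signal

  inp <- data.table::copy(vit)[, `:=`(encounter_setting = "inpatient",
                                      systolic = 180, diastolic = 110)]
  expect_equal(nrow(aggregate_daily(inp, NULL, specs$HTN)), 0)

  lab <- data.table::data.table(
    patient_id = "p1", specimen_date = as.Date("2015-01-01"),
    code = "4548-4", value = c(6.4, 7.0))
  dd <- aggregate_daily(NULL, lab, specs$DM)
  expect_equal(dd$min_value, 6.4)
  expect_equal(nrow(detect_signals(dd, specs$DM)), 0)
})

test_that("aggregate_daily is invariant to input row order", {
  set.seed(7)
  vit <- data.table::data.table(
    patient_id = sample(c("a", "b"), 40, TRUE),
    measure_date = as.Date("2015-01-01") + sample(0:5, 40, TRUE),
    systolic = sample(110:190, 40, TRUE), diastolic = sample(60:110, 40, TRUE),
    encounter_setting = sample(c("outpatient", "inpatient"), 40, TRUE))
  a <- aggregate_daily(vit, NULL, specs$HTN)
  b <- aggregate_daily(vit[sample(.N)], NULL, specs$HTN)
  expect_equal(a, b)
})

test_that("detect_signals applies inclusive thresholds", {
  daily <- data.table::data.table(
    patient_id = "p", date = as.Date("2015-01-01") + 0:2,
    min_systolic = c(142, 120, 139), min_diastolic = c(80, 90, 89))
  sig <- detect_signals(daily, specs$HTN)
  expect_equal(sig$date, as.Date("2015-01-01") + 0:1)  # 142>=140; dia 90>=90; (139,89) no

  ldl <- data.table::data.table(patient_id = "p", date = as.Date("2015-01-01") + 0:1,
                                min_value = c(129.9, 130))
  expect_equal(detect_signals(ldl, specs$HLD)$date, as.Date("2015-01-02"))
})

test_that("compute_diagnosis spec examples", {
  base <- as.Date("2015-01-01")
  mk <- function(days) data.table::data.table(patient_id = "p", date = base + days)
  expect_equal(nrow(compute_diagnosis(mk(c(0, 29)), specs$HTN)), 0)
  r <- compute_diagnosis(mk(c(0, 30)), specs$HTN)
  expect_equal(r$first_signal_date, base)
  expect_equal(r$second_signal_date, base + 30)
  expect_equal(compute_diagnosis(mk(c(0, 10, 40)), specs$HTN)$second_signal_date,
               base + 40)
  expect_equal(compute_diagnosis(mk(c(0, 10, 39, 45)), specs$HTN)$second_signal_date,
               base + 39)
})

test_that("compute_diagnosis matches the brute-force pair oracle on random series", {
  set.seed(101)
  base <- as.Date("2014-06-01")
  for (rep in 1:200) {
    sep <- sample(c(0L, 15L, 30L), 1)
    spec <- condition_spec("HTN", min_separation_days = sep)
    n <- sample(0:12, 1)
    dates <- base + sample(0:200, n)
    sig <- data.table::data.table(patient_id = "p", date = dates)
    got <- compute_diagnosis(sig, spec)
    want <- bf_signal_pair(dates, sep)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got$first_signal_date, want$first)
      expect_equal(got$second_signal_date, want$second)
    }
  }
})

test_that("adding a signal after the second signal never changes the result", {
  set.seed(202)
  base <- as.Date("2015-01-01")
  for (rep in 1:50) {
    dates <- base + sort(sample(0:300, sample(2:10, 1)))
    sig <- data.table::data.table(patient_id = "p", date = dates)
    got <- compute_diagnosis(sig, specs$HTN)
    if (nrow(got) == 0) next
    extra <- data.table::rbindlist(list(
      sig, data.table::data.table(patient_id = "p",
                                  date = got$second_signal_date + sample(1:500, 1))))
    expect_equal(compute_diagnosis(extra, specs$HTN), got)
  }
})

test_that("fewer than two distinct signal dates never yields a diagnosis", {
  base <- as.Date("2015-01-01")
  sig <- data.table::data.table(patient_id = "p", date = rep(base, 5))
  expect_equal(nrow(compute_diagnosis(sig, specs$DM)), 0)
  expect_equal(nrow(compute_diagnosis(sig[0], specs$DM)), 0)
})
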