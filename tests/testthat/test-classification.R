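D <- function(x) as.Date(x)

mk_computed <- function(pid, first, second) data.table::data.table(
  patient_id = pid, first_signal_date = D(first), second_signal_date = D(second))
mk_structured <- function(pid, date, src = "provider") data.table::data.table(
  patient_id = pid, condition = "HTN", first_dx_date = D(date), dx_source = src)
mk_enc <- function(pid, date) data.table::data.table(
  patient_id = pid, last_encounter_date = D(date))

test_that("boundary examples: category, duration, event", {
  # dx on the second-signal date -> eventual, duration 0
  c1 <- classify_patients(mk_computed("p", "2015-01-01", "2015-03-01"),
                          mk_structured("p", "2015-03-01"), mk_enc("p", "2016-01-01"))
  expect_equal(c1$category, "eventual")
  expect_equal(c1$duration_days, 0L)
  expect_true(c1$event)

  # dx strictly before first signal -> pre_existing
  c2 <- classify_patients(mk_computed("p", "2015-01-01", "2015-03-01"),
                          mk_structured("p", "2014-12-31"), mk_enc("p", "2016-01-01"))
  expect_equal(c2$category, "pre_existing")
  expect_true(is.na(c2$duration_days))

  # dx on the first-signal date -> early (not pre_existing)
  c3 <- classify_patients(mk_computed("p", "2015-01-01", "2015-03-01"),
                          mk_structured("p", "2015-01-01"), mk_enc("p", "2016-01-01"))
  expect_equal(c3$category, "early")

  # dx between the signals -> early
  c4 <- classify_patients(mk_computed("p", "2015-01-01", "2015-03-01"),
                          mk_structured("p", "2015-02-01"), mk_enc("p", "2016-01-01"))
  expect_equal(c4$category, "early")

  # no dx -> never, censored at last encounter
  c5 <- classify_patients(mk_computed("p", "2015-01-01", "2015-03-01"),
                          NULL, mk_enc("p", "2016-03-01"))
  expect_equal(c5$category, "never")
  expect_equal(c5$duration_days, 366L)
  expect_false(c5$event)
})

test_that("never-diagnosed with last encounter before second signal floors at 0", {
  expect_warning(
    c6 <- classify_patients(mk_computed("p", "2015-01-01", "2015-03-01"),
                            NULL, mk_enc("p", "2015-02-01")),
    "floored")
  expect_equal(c6$duration_days, 0L)
})

test_that("categories partition the computed cohort; durations nonnegative", {
  set.seed(505)
  n <- 300
  first <- D("2014-01-01") + sample(0:800, n, TRUE)
  second <- first + 30 + sample(0:200, n, TRUE)
  computed <- data.table::data.table(patient_id = sprintf("p%03d", 1:n),
                                     first_signal_date = first,
                                     second_signal_date = second)
  has_dx <- runif(n) < 0.7
  dx_date <- first + sample(-200:400, n, TRUE)
  structured <- data.table::data.table(
    patient_id = sprintf("p%03d", 1:n), condition = "HTN",
    first_dx_date = dx_date, dx_source = "provider")[has_dx]
  # keep only structurally valid eventual dx (>= second or anywhere else)
  enc <- data.table::data.table(patient_id = sprintf("p%03d", 1:n),
                                last_encounter_date = second + sample(0:800, n, TRUE))
  cls <- classify_patients(computed, structured, enc)
  expect_equal(nrow(cls), n)
  expect_setequal(unique(cls$category),
                  intersect(c("pre_existing", "early", "eventual", "never"),
                            unique(cls$category)))
  expect_equal(sum(table(cls$category)), n)
  expect_true(all(cls$duration_days[!is.na(cls$duration_days)] >= 0))
  expect_true(all(cls[event == TRUE, category] == "eventual"))
  # classify is deterministic
  expect_equal(cls, classify_patients(computed, structured, enc))
})

test_that("exclusion_filter keeps only eventual and never", {
  computed <- mk_computed(c("a", "b", "c", "d"),
                          rep("2015-01-01", 4), rep("2015-03-01", 4))
  structured <- data.table::rbindlist(list(
    mk_structured("a", "2014-01-01"),     # pre_existing
    mk_structured("b", "2015-02-01"),     # early
    mk_structured("c", "2015-09-01")))    # eventual
  enc <- mk_enc(c("a", "b", "c", "d"), rep("2016-01-01", 4))
  cls <- classify_patients(computed, structured, enc)
  kept <- exclusion_filter(cls)
  expect_setequal(kept$patient_id, c("c", "d"))
  expect_setequal(kept$category, c("eventual", "never"))

  all_pre <- cls[category == "pre_existing"]
  expect_warning(empty <- exclusion_filter(all_pre), "empty")
  expect_equal(nrow(empty), 0)
  expect_equal(nrow(exclusion_filter(cls[0])), 0)
})
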