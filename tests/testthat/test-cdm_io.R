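test_that("read_cdm_tables drops and counts malformed rows, maps OD/BI/CL", {
  dir <- withr::local_tempdir()
  writeLines(c("PATID,MEASURE_DATE,SYSTOLIC,DIASTOLIC,ENC_TYPE",
               "p1,2015-01-02,150,85,AV",
               "p1,not-a-date,140,90,AV",
               "p2,2015-03-04,999,60,AV"),   # systolic out of sanity range
             file.path(dir, "vital.csv"))
  writeLines(c("PATID,ADMIT_DATE,DX,DX_TYPE,DX_SOURCE",
               "p1,2015-01-02,I10,10,OD",
               "p1,2015-01-03,I10,10,BI",
               "p1,2015-01-04,401.1,09,CL",
               "p1,2015-01-05,I10,10,XX"),   # unmapped source
             file.path(dir, "diagnosis.csv"))
  tabs <- read_cdm_tables(list(vital = file.path(dir, "vital.csv"),
                               diagnosis = file.path(dir, "diagnosis.csv")))
  expect_equal(nrow(tabs$vital), 2)          # bad date dropped; 999 nulled, dia kept
  expect_true(is.na(tabs$vital[patient_id == "p2", systolic]))
  rep <- attr(tabs, "load_report")
  expect_equal(rep$vital$bad_date_or_id, 1L)
  expect_equal(rep$vital$out_of_range_systolic, 1L)
  expect_equal(tabs$diagnosis$source, c("provider", "billing", "claims"))
  expect_equal(rep$diagnosis$unmapped_source, 1L)
})

test_that("missing file and missing column are fatal; empty table warns", {
  dir <- withr::local_tempdir()
  expect_error(read_cdm_tables(list(vital = file.path(dir, "nope.csv"))),
               "file not found")
  writeLines("PATID,WRONG", file.path(dir, "vital.csv"))
  expect_error(read_cdm_tables(list(vital = file.path(dir, "vital.csv"))),
               "MEASURE_DATE")
  writeLines("PATID,MEASURE_DATE,SYSTOLIC,DIASTOLIC,ENC_TYPE",
             file.path(dir, "empty.csv"))
  expect_warning(read_cdm_tables(list(vital = file.path(dir, "empty.csv"))),
                 "loaded empty")
})

test_that("write/read round-trips a synthetic extract exactly", {
  gen <- synth_generate(synth_config(n_patients = 100, seed = 11))
  dir <- withr::local_tempdir()
  write_cdm_tables(gen$tables, dir)
  back <- read_cdm_tables(list(
    demographic = file.path(dir, "demographic.csv"),
    encounter = file.path(dir, "encounter.csv"),
    diagnosis = file.path(dir, "diagnosis.csv"),
    vital = file.path(dir, "vital.csv"),
    lab_result = file.path(dir, "lab_result.csv")))
  for (tb in c("demographic", "encounter", "diagnosis", "vital", "lab_result")) {
    expect_equal(as.data.frame(back[[tb]]), as.data.frame(gen$tables[[tb]]),
                 info = tb)
  }
  expect_length(attr(back, "load_report"), 0)
})

test_that("empty collections write header-only CSVs that read back empty", {
  dir <- withr::local_tempdir()
  write_cdm_tables(empty_cdm_tables(), dir)
  expect_equal(length(readLines(file.path(dir, "vital.csv"))), 1L)
  expect_warning(back <- read_cdm_tables(list(vital = file.path(dir, "vital.csv"))),
                 "loaded empty")
  expect_equal(nrow(back$vital), 0)
})

test_that("filter_window honors inclusive per-kind cutoffs and is idempotent", {
  w <- study_window("2012-01-01", "2018-08-11", "2019-02-10")
  dt <- data.table::data.table(
    patient_id = "p",
    measure_date = as.Date(c("2011-12-31", "2012-01-01", "2018-08-11",
                             "2018-08-12", "2019-02-10", "2019-02-11")))
  m <- filter_window(dt, w, "measurement")
  expect_equal(m$measure_date, as.Date(c("2012-01-01", "2018-08-11")))
  d <- filter_window(dt, w, "diagnosis")
  expect_equal(d$measure_date,
               as.Date(c("2012-01-01", "2018-08-11", "2018-08-12", "2019-02-10")))
  expect_equal(filter_window(m, w, "measurement"), m)   # idempotent
  # order-preserving on shuffled input
  shuf <- dt[c(5, 2, 3, 1, 6, 4)]
  expect_equal(filter_window(shuf, w, "diagnosis")$measure_date,
               as.Date(c("2019-02-10", "2012-01-01", "2018-08-11", "2018-08-12")))
})

test_that("study_window validates ordering and dates", {
  expect_error(study_window("2019-01-01", "2012-01-01", "2020-01-01"))
  expect_error(study_window("garbage", "2012-01-01", "2020-01-01"))
})
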