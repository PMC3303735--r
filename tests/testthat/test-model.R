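make_small_warehouse <- function() {
  wh <- new_warehouse()
  wh$patients <- data.frame(patient_id = c("PT-1", "PT-2"),
                            sex = c("F", "F"),
                            birth_date = c("1950-01-01", "1960-06-15"),
                            vital_status = c("alive", "deceased"),
                            death_date = c(NA, "2010-03-01"),
                            stringsAsFactors = FALSE)
  wh$visits <- data.frame(visit_id = c("V-1", "V-2"),
                          patient_id = c("PT-1", "PT-2"),
                          start_date = c("2005-02-01", "2006-05-01"),
                          end_date = c("2005-02-03", "2006-05-01"),
                          location_code = "ONC-WARD",
                          stringsAsFactors = FALSE)
  wh$providers <- data.frame(provider_id = "PROV-PATH",
                             name = "Pathology unit",
                             department = "Pathology",
                             stringsAsFactors = FALSE)
  wh$concepts <- data.frame(
    concept_code = c("DIM:BIOBANK", "BB:TISSUE", "BMK:KI67"),
    concept_path = c("\\Biobank\\", "\\Biobank\\Tissue\\", "\\Ki-67\\"),
    name = c("Biobank", "Tissue", "Ki-67"),
    level = c(1L, 2L, 1L), source = c("BIOBANK", "BIOBANK", "BIOMARKER"),
    stringsAsFactors = FALSE)
  wh
}

test_that("upsert is key-idempotent and replaces on collision", {
  wh <- make_small_warehouse()
  f <- observation_fact("PT-1", "V-1", "BMK:KI67", "PROV-PATH",
                        "2005-02-01", "numeric", 25, units = "%")
  wh <- upsert_fact(wh, f)
  expect_equal(nrow(wh$facts), 1L)
  wh <- upsert_fact(wh, f)
  expect_equal(nrow(wh$facts), 1L)
  f2 <- f
  f2$numeric_value <- 30
  wh <- upsert_fact(wh, f2)
  expect_equal(nrow(wh$facts), 1L)
  expect_equal(wh$facts$numeric_value, 30)
})

test_that("unresolved foreign keys are integrity errors naming the key", {
  wh <- make_small_warehouse()
  f <- observation_fact("PT-1", "V-1", "NOPE", "PROV-PATH", "2005-02-01")
  err <- tryCatch(upsert_fact(wh, f), condition = function(e) e)
  expect_s3_class(err, "dw_integrity_error")
  expect_match(conditionMessage(err), "NOPE")
  expect_match(conditionMessage(err), "concept")
  ## auto-register admits the fact under \Unclassified\
  wh2 <- upsert_fact(wh, f, auto_register = TRUE)
  expect_equal(nrow(wh2$facts), 1L)
  expect_equal(nrow(integrity_check(wh2)), 0L)
})

test_that("integrity_check flags corrupted rows and passes clean data", {
  wh <- make_small_warehouse()
  f <- observation_fact("PT-1", "V-1", "BB:TISSUE", "PROV-PATH",
                        "2005-02-01")
  wh <- upsert_fact(wh, f)
  expect_equal(nrow(integrity_check(wh)), 0L)

  broken <- wh
  broken$patients <- broken$patients[-1, ]
  v <- integrity_check(broken)
  expect_gte(nrow(v), 1L)
  expect_true(any(v$rule == "patient_id resolves"))

  bad_level <- wh
  bad_level$concepts$level[2] <- 5L
  expect_true(any(integrity_check(bad_level)$rule ==
                    "level = number of path segments"))

  bad_dead <- wh
  bad_dead$patients$death_date[2] <- NA
  expect_true(any(integrity_check(bad_dead)$rule ==
                    "death_date required when deceased"))
})

test_that("counts equal table scans and biobank membership", {
  wh <- make_small_warehouse()
  cts <- warehouse_counts(wh)
  expect_equal(cts$n_facts, 0L)
  expect_equal(cts$n_biobanked_patients, 0L)
  wh <- upsert_fact(wh, observation_fact("PT-1", "V-1", "BB:TISSUE",
                                         "PROV-PATH", "2005-02-01"))
  wh <- upsert_fact(wh, observation_fact("PT-2", "V-2", "BMK:KI67",
                                         "PROV-PATH", "2006-05-01",
                                         "numeric", 10, units = "%"))
  cts <- warehouse_counts(wh)
  expect_equal(cts$n_patients, 2L)
  expect_equal(cts$n_visits, 2L)
  expect_equal(cts$n_facts, 2L)
  expect_equal(cts$n_concepts, 3L)
  expect_equal(cts$n_biobanked_patients, 1L)
})

test_that("warehouse round-trips through its delimited export", {
  pipe <- run_pipeline(15, seed = 11)
  dir <- withr::local_tempdir()
  export_warehouse(pipe$warehouse, dir)
  back <- import_warehouse(dir)
  for (tb in c("patients", "visits", "providers", "concepts", "facts"))
    expect_equal(back[[tb]], pipe$warehouse[[tb]],
                 ignore_attr = TRUE)
  expect_equal(warehouse_counts(back), warehouse_counts(pipe$warehouse))
})

test_that("counts on a synthetic cohort match generator bookkeeping", {
  pipe <- run_pipeline(50, seed = 4)
  expect_equal(warehouse_counts(pipe$warehouse), pipe$sim$truth$tallies)
})
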