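specimen_row <- function(id, patient, consent = TRUE, ts = "2011-06-01T09:00:00",
                         material = "tissue") {
  data.frame(pu_specimen_id = id, pu_patient_id = patient,
             material_type = material, fridge_position = "FR1-S1-B01",
             consent_research = consent, project = "BREAST-01",
             sample_type = "primary", creation_date = "2011-05-30",
             description = "FFPE block from surgical resection",
             updated_at = ts, given_name = "Dedapa", family_name = "Sanera",
             stringsAsFactors = FALSE)
}

test_that("sync admits consented specimens, skips others, quarantines junk", {
  pu <- rbind(specimen_row("SPC-1", "MRN-1"), specimen_row("SPC-2", "MRN-1"),
              specimen_row("SPC-3", "MRN-2"), specimen_row("SPC-4", "MRN-3"),
              specimen_row("SPC-5", "MRN-4", consent = FALSE),
              specimen_row("SPC-6", "MRN-5", material = "granite"))
  set.seed(1)
  out <- sync_pu_to_biobank(pu, new_biobank(), new_lookup(),
                            new_sync_state())
  expect_equal(nrow(out$biobank), 4L)
  expect_equal(nrow(out$lookup$barcodes), 4L)
  expect_equal(sum(out$log$action == "skipped"), 1L)
  expect_equal(sum(out$log$action == "quarantined"), 1L)
  expect_true(all(out$biobank$consent_research))

  ## rerun with unchanged source: nothing new
  out2 <- sync_pu_to_biobank(pu, out$biobank, out$lookup, out$state)
  expect_equal(nrow(out2$biobank), 4L)
  expect_equal(out2$state$last_sync_timestamp, out$state$last_sync_timestamp)

  ## a newer specimen is picked up incrementally
  pu2 <- rbind(pu, specimen_row("SPC-7", "MRN-2",
                                ts = "2011-06-02T10:00:00"))
  out3 <- sync_pu_to_biobank(pu2, out2$biobank, out2$lookup, out2$state)
  expect_equal(nrow(out3$biobank), 5L)
})

test_that("the concept dimension satisfies all path invariants", {
  cd <- build_concept_dimension()
  wh <- new_warehouse()
  wh$concepts <- cd
  expect_equal(nrow(integrity_check(wh)), 0L)
  expect_false(anyDuplicated(cd$concept_code) > 0)
  for (branch in c("\\SNOMED\\", "\\TNM\\", "\\Biomarkers\\", "\\Biobank\\",
                   "\\Demographics\\"))
    expect_gte(nrow(concept_descendants(cd, branch)), 2L)
})

test_that("load maps one patient's report and sample to the expected facts", {
  ## 1 patient, 1 report (2 snomed + ki67 + TNM), 1 tissue sample:
  ## 2 demographics + 2 snomed + 3 TNM + 1 ki67 + 1 material + 2 meta = 11
  his <- list(
    patients = data.frame(pu_patient_id = "MRN-1", sex = "F",
                          birth_date = "1955-05-05", vital_status = "alive",
                          death_date = NA_character_,
                          stringsAsFactors = FALSE),
    visits = data.frame(visit_id = "V-1", pu_patient_id = "MRN-1",
                        start_date = "2011-05-30", end_date = "2011-05-31",
                        location_code = "SURGERY", stringsAsFactors = FALSE))
  res <- extraction_result(
    name = "RPT-1", date = "2011-05-30", type = "histological", ki67 = 25,
    state = tnm_stage(t = "2", n = "1", m = "0", prefix = "p"),
    snomed = data.frame(code = c("M-85003", "M-85202"),
                        name = c("Infiltrating duct carcinoma",
                                 "Lobular carcinoma in situ"),
                        stringsAsFactors = FALSE))
  set.seed(2)
  sy <- sync_pu_to_biobank(specimen_row("SPC-1", "MRN-1"), new_biobank(),
                           new_lookup(), new_sync_state())
  out <- load_warehouse(new_warehouse(), build_concept_dimension(), his,
                        list(res), sy$biobank, sy$lookup,
                        data.frame(report_id = "RPT-1",
                                   pu_patient_id = "MRN-1",
                                   stringsAsFactors = FALSE))
  expect_equal(out$report$facts_written, 11L)
  expect_equal(out$report$skipped, 0L)
  expect_equal(length(out$report$orphans), 0L)
  expect_equal(nrow(integrity_check(out$warehouse)), 0L)
  f <- out$warehouse$facts
  expect_setequal(
    f$concept_code,
    c("DEM:SEX:F", "DEM:VITAL:ALIVE", "M-85003", "M-85202", "TNM:T2",
      "TNM:N1", "TNM:M0", "BMK:KI67", "BB:TISSUE", "BB:PROJ:BREAST-01",
      "BB:STYPE:PRIMARY"))
  expect_equal(f$numeric_value[f$concept_code == "BMK:KI67"], 25)
  expect_equal(f$units[f$concept_code == "BMK:KI67"], "%")

  ## unknown snomed code: fact skipped with a log line
  res2 <- res
  res2$snomed <- rbind(res2$snomed,
                       data.frame(code = "M-99999", name = "Unknown",
                                  stringsAsFactors = FALSE))
  out2 <- load_warehouse(new_warehouse(), build_concept_dimension(), his,
                         list(res2), sy$biobank, sy$lookup,
                         data.frame(report_id = "RPT-1",
                                    pu_patient_id = "MRN-1",
                                    stringsAsFactors = FALSE))
  expect_equal(out2$report$skipped, 1L)
  expect_equal(out2$report$facts_written, 11L)

  ## orphan extraction: patient absent from HIS
  out3 <- load_warehouse(new_warehouse(), build_concept_dimension(), his,
                         list(res), sy$biobank, sy$lookup,
                         data.frame(report_id = "RPT-1",
                                    pu_patient_id = "MRN-404",
                                    stringsAsFactors = FALSE))
  expect_equal(out3$report$orphans, "RPT-1")
})

test_that("load_report arithmetic reflects the load result", {
  rep <- load_report(list(facts_written = 11, skipped = 1,
                          orphans = c("RPT-9"), quarantined = 2))
  expect_equal(rep$facts_written, 11L)
  expect_equal(rep$skipped, 1L)
  expect_equal(rep$orphans, 1L)
  expect_equal(rep$quarantined, 2L)
})

test_that("pipeline conserves ground truth and re-load is idempotent", {
  pipe <- run_pipeline(40, seed = 6)
  expect_equal(warehouse_counts(pipe$warehouse), pipe$sim$truth$tallies)
  again <- load_warehouse(pipe$warehouse, build_concept_dimension(),
                          pipe$sim$his, pipe$extractions, pipe$sync$biobank,
                          pipe$lookup, pipe$sim$report_map)
  expect_equal(warehouse_counts(again$warehouse),
               warehouse_counts(pipe$warehouse))
  a <- again$warehouse$facts[order(oncodw:::fact_key(again$warehouse$facts)), ]
  b <- pipe$warehouse$facts[order(oncodw:::fact_key(pipe$warehouse$facts)), ]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("non-consented specimens never reach warehouse exports", {
  pipe <- run_pipeline(150, seed = 23)
  spc <- pipe$sim$pu_specimens
  if (any(!spc$consent_research)) {
    ## every biobank payload resolves to a consented specimen's donor set
    expect_true(all(pipe$sync$biobank$consent_research))
    n_nonconsented <- sum(!spc$consent_research)
    expect_equal(nrow(pipe$sync$biobank),
                 nrow(spc) - n_nonconsented)
  }
  dir <- withr::local_tempdir()
  export_warehouse(pipe$warehouse, dir)
  bb_codes <- pipe$warehouse$concepts$concept_code[
    startsWith(pipe$warehouse$concepts$concept_path, "\\Biobank\\")]
  n_sample_facts <- sum(pipe$warehouse$facts$concept_code %in% bb_codes)
  expect_equal(n_sample_facts, 3L * sum(spc$consent_research))
})
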