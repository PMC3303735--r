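test_that("panels OR items, constraints bind to the matching fact", {
  pipe <- run_pipeline(60, seed = 15)
  wh <- pipe$warehouse
  cd <- wh$concepts

  ## root panel: everyone with at least one fact (= everyone; all patients
  ## carry demographics)
  all_ids <- eval_panel(query_panel("\\Demographics\\"), wh, cd)
  expect_setequal(all_ids, wh$patients$patient_id)

  ## Ki-67 >= 20: brute-force comparison against the raw fact table
  got <- eval_panel(query_panel("\\Biomarkers\\Ki-67\\", value_op = ">=",
                                value = 20), wh, cd)
  f <- wh$facts
  want <- unique(f$patient_id[f$concept_code == "BMK:KI67" &
                                f$value_type == "numeric" &
                                !is.na(f$numeric_value) &
                                f$numeric_value >= 20])
  expect_setequal(got, want)

  ## inverted empty-match panel returns all patients
  none <- query_panel("\\Biomarkers\\Ki-67\\", value_op = ">=", value = 101,
                      invert = TRUE)
  expect_setequal(eval_panel(none, wh, cd), wh$patients$patient_id)

  ## value constraint outside the numeric branch is a type error
  expect_error(eval_panel(query_panel("\\Biobank\\", value_op = ">=",
                                      value = 1), wh, cd),
               class = "dw_type_error")
})

test_that("run_query intersects panels; always-false panel empties it", {
  pipe <- run_pipeline(60, seed = 16)
  wh <- pipe$warehouse
  cd <- wh$concepts
  p1 <- query_panel("\\SNOMED\\")
  expect_setequal(run_query(query_definition(p1), wh, cd)$patient_ids,
                  eval_panel(p1, wh, cd))
  both <- run_query(query_definition(p1, query_panel("\\Biobank\\Tissue\\")),
                    wh, cd)$patient_ids
  f <- wh$facts
  tissue <- unique(f$patient_id[f$concept_code == "BB:TISSUE"])
  snomed_codes <- cd$concept_code[startsWith(cd$concept_path, "\\SNOMED\\")]
  diag <- unique(f$patient_id[f$concept_code %in% snomed_codes])
  expect_setequal(both, intersect(diag, tissue))
  never <- query_panel("\\Biomarkers\\Ki-67\\", value_op = ">=", value = 101)
  expect_length(run_query(query_definition(p1, never), wh, cd)$patient_ids, 0L)
})

test_that("query engine equals the brute-force oracle on random definitions", {
  pipe <- run_pipeline(80, seed = 17)
  wh <- pipe$warehouse
  cd <- wh$concepts
  set.seed(99)
  for (i in 1:40) {
    def <- random_query_definition(cd)
    expect_identical(run_query(def, wh, cd)$patient_ids,
                     oracle_run_query(def, wh, cd))
  }
})

test_that("monotonicity and hierarchy-union properties hold", {
  pipe <- run_pipeline(60, seed = 18)
  wh <- pipe$warehouse
  cd <- wh$concepts
  base <- query_panel("\\SNOMED\\Neoplasm and hamartoma\\Neoplasm malignant\\")
  r0 <- run_query(query_definition(base), wh, cd)$patient_ids
  ## appending a non-inverted panel never enlarges the set
  r1 <- run_query(query_definition(base, query_panel("\\Biobank\\")),
                  wh, cd)$patient_ids
  expect_true(all(r1 %in% r0))
  ## replacing a concept by its ancestor never shrinks it
  r2 <- run_query(query_definition(
    query_panel("\\SNOMED\\Neoplasm and hamartoma\\")), wh, cd)$patient_ids
  expect_true(all(r0 %in% r2))
  ## parent result = union over children (+ facts at the parent itself)
  parent <- "\\SNOMED\\Neoplasm and hamartoma\\"
  pp <- oncodw:::parent_path(cd$concept_path)
  kids <- cd$concept_path[!is.na(pp) & pp == parent]
  union_kids <- unique(unlist(lapply(kids, function(k)
    eval_panel(query_panel(k), wh, cd))))
  at_parent <- wh$facts$patient_id[wh$facts$concept_code %in%
    cd$concept_code[cd$concept_path == parent]]
  expect_setequal(eval_panel(query_panel(parent), wh, cd),
                  union(union_kids, unique(at_parent)))
})

test_that("patient sets and query definitions round-trip through files", {
  pipe <- run_pipeline(30, seed = 19)
  wh <- pipe$warehouse
  def <- query_definition(
    query_panel(c("\\SNOMED\\", "\\Biobank\\Tissue\\"),
                value_op = NULL, date_from = "2003-01-01",
                date_to = "2010-12-31"),
    query_panel("\\Biomarkers\\Ki-67\\", value_op = "between", value = 10,
                value2 = 60, invert = FALSE))
  ps <- run_query(def, wh, created_at = "2011-01-01T12:00:00")
  f <- withr::local_tempfile(fileext = ".txt")
  save_patient_set(ps, f)
  back <- load_patient_set(f)
  expect_identical(back$patient_ids, ps$patient_ids)
  expect_identical(back$provenance$created_at, ps$provenance$created_at)
  ## the stored provenance definition re-evaluates to the same set
  expect_identical(
    run_query(back$provenance$definition, wh)$patient_ids, ps$patient_ids)

  qf <- withr::local_tempfile(fileext = ".txt")
  save_query_definition(def, qf)
  expect_identical(run_query(load_query_definition(qf), wh)$patient_ids,
                   ps$patient_ids)

  ## empty set round-trip
  empty <- run_query(query_definition(
    query_panel("\\Biomarkers\\Ki-67\\", value_op = ">=", value = 101)),
    wh, created_at = "2011-01-01T12:00:00")
  f2 <- withr::local_tempfile(fileext = ".txt")
  save_patient_set(empty, f2)
  expect_length(load_patient_set(f2)$patient_ids, 0L)

  ## truncated / foreign file
  f3 <- withr::local_tempfile(fileext = ".txt")
  writeLines("PT-000001", f3)
  expect_error(load_patient_set(f3), class = "dw_parse_error")
})
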