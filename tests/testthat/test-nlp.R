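sample_report <- function() {
  paste(c("REPORT ID: RPT-000001",
          "REPORT DATE: 2007-03-14",
          "REPORT TYPE: HISTOLOGICAL",
          "SPECIMEN NUMBER: S-2007/0001",
          "ANAMNESIS:",
          "Palpable nodule; an earlier specimen elsewhere showed Ki-67 70%.",
          "MACROSCOPIC DESCRIPTION:",
          "Lumpectomy specimen, single nodular lesion.",
          "DIAGNOSIS:",
          "Infiltrating duct carcinoma (M-85003).",
          "Lobular carcinoma in situ (M-85202).",
          "TNM stage: pT2 N1 M0. Grade: G2.",
          "Estrogen receptors: 90%. Progesterone receptors: 0%.",
          "Ki-67: 10%. c-erbB2 (DAKO): 3+."),
        collapse = "\n")
}

test_that("sectionizer splits the template and demands a diagnosis header", {
  cfg <- extraction_config()
  doc <- sectionize(sample_report(), cfg)
  expect_setequal(names(doc$sections),
                  c("ANAMNESIS", "MACROSCOPIC", "DIAGNOSIS"))
  expect_match(doc$sections$DIAGNOSIS, "M-85003", fixed = TRUE)
  expect_false(grepl("M-85003", doc$sections$ANAMNESIS, fixed = TRUE))
  expect_equal(doc$report_id, "RPT-000001")
  expect_equal(doc$report_date, "2007-03-14")

  only_diag <- "REPORT ID: RPT-9\nDIAGNOSIS:\nFibroadenoma (M-90100)."
  doc2 <- sectionize(only_diag, cfg)
  expect_equal(names(doc2$sections), "DIAGNOSIS")
  expect_match(doc2$sections$DIAGNOSIS, "M-90100", fixed = TRUE)

  err <- tryCatch(sectionize("no headers at all", cfg, report_id = "R-7"),
                  condition = function(e) e)
  expect_s3_class(err, "dw_missing_section")
  expect_match(conditionMessage(err), "R-7")
})

test_that("snomed extraction is lexicon-gated, ordered, de-duplicated", {
  lex <- snomed_lexicon()
  out <- extract_snomed("first M-85202 then M-85003 and again M-85202", lex)
  expect_equal(out$matched$code, c("M-85202", "M-85003"))
  expect_equal(out$matched$name,
               c("Lobular carcinoma in situ", "Infiltrating duct carcinoma"))
  expect_equal(nrow(extract_snomed("", lex)$matched), 0L)
  odd <- extract_snomed("shaped but unknown M-99999", lex)
  expect_equal(nrow(odd$matched), 0L)
  expect_equal(odd$unknown, "M-99999")
})

test_that("TNM grammar parses prefixes, subdivisions and in-situ", {
  s <- extract_tnm("stage pT2 N1 M0 reported")
  expect_equal(s$prefix, "p")
  expect_equal(s$t, "2")
  expect_equal(s$n, "1")
  expect_equal(s$m, "0")
  expect_equal(extract_tnm("Tis N0 M0")$t, "is")
  expect_equal(extract_tnm("ypT4b N2a MX")$prefix, "yp")
  expect_equal(extract_tnm("ypT4b N2a MX")$t, "4b")
  expect_null(extract_tnm("no staging here"))
  expect_warning(extract_tnm("pT2 N1 M0 but also pT3 N0 M0"),
                 class = "dw_tnm_ambiguity")
  ## serialized form round-trips for the whole vocabulary grid
  for (t in oncodw:::TNM_T_VALUES)
    for (n in c("X", "1a", "3"))
      for (p in c(NA, "p", "yp")) {
        st <- tnm_stage(t = t, n = n, m = "0", prefix = p)
        back <- extract_tnm(format_tnm(st))
        expect_identical(format_tnm(back), format_tnm(st))
      }
})

test_that("biomarker patterns read percents, scores, grades and status", {
  cfg <- extraction_config()
  b <- extract_biomarkers(
    "Ki-67: 25%. c-erbB2 (DAKO): 3+. Grade: G1. ER: 80%. PgR: negative.",
    cfg)
  expect_equal(b$ki67, 25)
  expect_equal(b$c_erb_b2, 3L)
  expect_equal(b$grade, 1L)
  expect_equal(b$estrogens_receptors, 80)
  expect_true(is.na(b$progesterone_receptors))
  expect_equal(b$progesterone_receptors_status, "negative")
  err <- tryCatch(extract_biomarkers("ER 120%", cfg),
                  condition = function(e) e)
  expect_s3_class(err, "dw_range_error")
  expect_match(conditionMessage(err), "estrogens_receptors")
})

test_that("extraction uses only the diagnosis section", {
  txt <- paste(c("REPORT ID: RPT-000002",
                 "REPORT DATE: 2008-01-10",
                 "REPORT TYPE: HISTOLOGICAL",
                 "ANAMNESIS:",
                 "Earlier report: Ki-67 70%, code M-90100, stage pT4 N3 M1.",
                 "DIAGNOSIS:",
                 "Infiltrating duct carcinoma (M-85003). Ki-67: 10%."),
               collapse = "\n")
  res <- extract_report(txt)
  expect_equal(res$ki67, 10)
  expect_equal(res$snomed$code, "M-85003")
  expect_null(res$state)
})

test_that("full-template extraction is complete and deterministic", {
  res <- extract_report(sample_report())
  expect_equal(res$name, "RPT-000001")
  expect_equal(res$type, "histological")
  expect_equal(res$number, "S-2007/0001")
  expect_equal(res$estrogens_receptors, 90)
  expect_equal(res$progesterone_receptors, 0)
  expect_equal(res$ki67, 10)
  expect_equal(res$c_erb_b2, 3L)
  expect_equal(res$grade, 2L)
  expect_equal(format_tnm(res$state), "pT2 N1 M0")
  expect_equal(res$snomed$code, c("M-85003", "M-85202"))
  res2 <- extract_report(sample_report())
  expect_same_result(res, res2)
})

test_that("validation rejects out-of-range and inconsistent records", {
  expect_error(extraction_result(name = "R", date = "2001-01-01",
                                 type = "histological", ki67 = 150),
               class = "dw_validation_error")
  expect_error(extraction_result(name = "R", date = "2001-01-01",
                                 type = "other"),
               class = "dw_validation_error")
  expect_error(extraction_result(name = "R", date = "2001-01-01",
                                 type = "histological", c_erb_b2 = 7L),
               class = "dw_validation_error")
  err <- tryCatch(extraction_result(name = "R", date = "bad-date",
                                    type = "histological", grade = 9L),
                  condition = function(e) e)
  expect_true(all(c("date", "grade") %in% err$fields))
})
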