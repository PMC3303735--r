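## Rule-based extraction from semi-structured pathology reports.  Reports are
## generated by a data-entry process, so they carry a predictable skeleton: a
## metadata preamble, then labelled sections (anamnesis, macroscopic
## description, coded diagnosis).  The pipeline has two stages, mirroring
## section-aware clinical NLP systems: a sectionizer that isolates the coded
## diagnosis section, then per-field pattern extraction (SNOMED-style
## morphology codes, TNM stage, grade, ER/PR, Ki-67, HER-2 score) applied to
## that section only — narrative anamnesis/description text never reaches the
## field extractors.

TNM_T_VALUES <- c("X", "0", "is", "1", "1a", "1b", "1c", "2", "3",
                  "4", "4a", "4b", "4c", "4d")
TNM_N_VALUES <- c("X", "0", "1", "1a", "2", "2a", "3")
TNM_M_VALUES <- c("X", "0", "1")
TNM_PREFIXES <- c("c", "p", "yp")

TNM_PATTERN <- "(?:\\b(yp|p|c))?T(is|1[abc]?|4[abcd]?|[X023])[ ,]*N(1a?|2a?|[X03])[ ,]*M([X01])\\b"

#' Build an extraction configuration
#'
#' The configuration plays the role a pattern/config file plays in
#' section-aware clinical extraction pipelines: it carries the section header
#' aliases (English and Italian), the per-field regular expressions, the
#' SNOMED-style code surface pattern, the code lexicon, and the accepted date
#' formats.
#'
#' @param lexicon named character vector mapping codes to names; defaults to
#'   the packaged morphology lexicon.
#' @param date_formats date formats accepted in the report preamble, tried in
#'   order (ISO-8601 first, then day-first European numeric).
#' @return a list of class `extraction_config`.
#' @export
extraction_config <- function(lexicon = snomed_lexicon(),
                              date_formats = c("%Y-%m-%d", "%d/%m/%Y")) {
  if (!length(lexicon))
    dw_stop("dw_value_error", "SNOMED lexicon must be non-empty")
  structure(list(
    section_patterns = list(
      ANAMNESIS = "^[ \t]*(anamnesis|anamnesi|clinical history)[ \t]*:?[ \t]*$",
      MACROSCOPIC = "^[ \t]*(macroscopic description|descrizione macroscopica|gross description|macroscopy)[ \t]*:?[ \t]*$",
      DIAGNOSIS = "^[ \t]*(diagnosis|diagnosi|coded diagnosis)[ \t]*:?[ \t]*$"),
    diagnosis_label = "DIAGNOSIS",
    meta_patterns = list(
      name   = "report id[ \t]*[:=][ \t]*([A-Za-z0-9-]+)",
      date   = "report date[ \t]*[:=][ \t]*([0-9/-]+)",
      type   = "report type[ \t]*[:=][ \t]*(histological|cytological|istologico|citologico)",
      number = "specimen (?:number|no\\.?)[ \t]*[:=][ \t]*([A-Za-z0-9/-]+)"),
    field_patterns = list(
      estrogens_receptors = "(?:estrogens? receptors?|recettori estrogeni|\\bER\\b)[ \t]*[:=]?[ \t]*(\\d{1,3})[ \t]*%",
      estrogens_receptors_status = "(?:estrogens? receptors?|recettori estrogeni|\\bER\\b)[ \t]*[:=]?[ \t]*(positive|negative)",
      progesterone_receptors = "(?:progesterone receptors?|recettori progestinici|\\bPgR\\b|\\bPR\\b)[ \t]*[:=]?[ \t]*(\\d{1,3})[ \t]*%",
      progesterone_receptors_status = "(?:progesterone receptors?|recettori progestinici|\\bPgR\\b|\\bPR\\b)[ \t]*[:=]?[ \t]*(positive|negative)",
      ki67 = "Ki[- ]?67[ \t]*[:=]?[ \t]*(\\d{1,3})[ \t]*%",
      c_erb_b2 = "(?:c-?erb[- ]?B-?2|HER-?2(?:/neu)?)[ \t]*(?:\\(DAKO\\))?[ \t]*[:=]?[ \t]*([0-3])[ \t]*\\+?",
      grade = "(?:\\bG|grade[ \t]*[:=]?[ \t]*G?)([1-3])\\b"),
    snomed_pattern = "\\b[A-Z]-\\d{5}\\b",
    tnm_pattern = TNM_PATTERN,
    lexicon = lexicon,
    date_formats = date_formats), class = "extraction_config")
}

first_capture <- function(text, pattern, ignore_case = TRUE) {
  m <- regexec(pattern, text, perl = TRUE, ignore.case = ignore_case)
  hit <- regmatches(text, m)[[1]]
  if (length(hit) >= 2) hit[2] else NA_character_
}

parse_report_date <- function(x, formats) {
  if (is.na(x)) return(NA_character_)
  for (fmt in formats) {
    d <- as.Date(x, format = fmt)
    if (!is.na(d)) return(format(d, "%Y-%m-%d"))
  }
  NA_character_
}

#' Split a pathology report into labelled sections
#'
#' Header lines are recognized by the configured alias patterns
#' (case-insensitive, English and Italian).  Text before the first header is
#' the metadata preamble, from which the report id, date, type and specimen
#' number are read.  Field extraction downstream uses only the coded
#' diagnosis section; a report with no diagnosis header is rejected.
#'
#' @param raw_text full report text.
#' @param config an [extraction_config()].
#' @param report_id optional id used in error messages when the preamble
#'   carries none.
#' @return a list of class `report_document` with `report_id`, `report_date`,
#'   `raw_text`, `preamble` and `sections` (label -> text).
#' @export
sectionize <- function(raw_text, config = extraction_config(),
                       report_id = NULL) {
  stopifnot(is.character(raw_text), length(raw_text) == 1, nzchar(raw_text))
  lines <- strsplit(raw_text, "\n", fixed = TRUE)[[1]]
  label <- rep(NA_character_, length(lines))
  for (lab in names(config$section_patterns)) {
    hit <- grepl(config$section_patterns[[lab]], lines,
                 perl = TRUE, ignore.case = TRUE)
    label[hit & is.na(label)] <- lab
  }
  hdr_idx <- which(!is.na(label))
  preamble <- paste(lines[seq_len(if (length(hdr_idx)) hdr_idx[1] - 1
                                  else length(lines))], collapse = "\n")
  rid <- first_capture(preamble, config$meta_patterns$name) %||% NA_character_
  if (!is.null(report_id) && is.na(rid)) rid <- report_id
  sections <- list()
  if (length(hdr_idx)) {
    bounds <- c(hdr_idx, length(lines) + 1L)
    for (k in seq_along(hdr_idx)) {
      span <- lines[seq(hdr_idx[k] + 1L, bounds[k + 1L] - 1L)]
      if (bounds[k + 1L] - 1L < hdr_idx[k] + 1L) span <- character(0)
      sections[[label[hdr_idx[k]]]] <- paste(span, collapse = "\n")
    }
  }
  if (!config$diagnosis_label %in% names(sections))
    dw_stop("dw_missing_section",
            sprintf("no coded-diagnosis section found in report %s",
                    if (is.na(rid)) "<unknown>" else rid),
            report_id = rid)
  rdate <- parse_report_date(first_capture(preamble, config$meta_patterns$date),
                             config$date_formats)
  structure(list(report_id = rid, report_date = rdate, raw_text = raw_text,
                 preamble = preamble, sections = sections),
            class = "report_document")
}

#' Extract SNOMED-style codes from text
#'
#' Codes matched by the surface pattern and present in the lexicon are
#' returned with their lexicon name, in order of first appearance and
#' de-duplicated; pattern-shaped codes absent from the lexicon go to a
#' separate `unknown` vector.
#'
#' @param text text to scan (normally the diagnosis section).
#' @param lexicon named character vector `code -> name`.
#' @param pattern code surface pattern.
#' @return list with `matched` (data frame `code`, `name`) and `unknown`.
#' @export
extract_snomed <- function(text, lexicon,
                           pattern = extraction_config(lexicon)$snomed_pattern) {
  if (!length(lexicon))
    dw_stop("dw_value_error", "SNOMED lexicon must be non-empty")
  hits <- regmatches(text, gregexpr(pattern, text, perl = TRUE))[[1]]
  hits <- hits[!duplicated(hits)]
  known <- hits[hits %in% names(lexicon)]
  list(matched = data.frame(code = known,
                            name = unname(lexicon[known]),
                            stringsAsFactors = FALSE),
       unknown = hits[!hits %in% names(lexicon)])
}

#' Parse the first TNM stage mention
#'
#' Grammar: optional prefix (`c` clinical, `p` pathological, `yp`
#' post-therapy pathological), then `T`, `N` and `M` components drawn from
#' their closed vocabularies (e.g. `pT2 N1 M0`, `Tis N0 M0`).  When two
#' conflicting conformant mentions occur, the first wins and an ambiguity
#' warning is signalled.
#'
#' @param text text to scan.
#' @return a `tnm_stage` (fields `prefix`, `t`, `n`, `m`) or `NULL`.
#' @export
extract_tnm <- function(text) {
  m <- gregexpr(TNM_PATTERN, text, perl = TRUE)
  full <- regmatches(text, m)[[1]]
  if (!length(full)) return(NULL)
  if (length(unique(full)) > 1)
    dw_warn("dw_tnm_ambiguity",
            sprintf("conflicting TNM mentions ('%s' vs '%s'); first taken",
                    full[1], unique(full)[2]))
  parts <- regmatches(full[1], regexec(TNM_PATTERN, full[1], perl = TRUE))[[1]]
  tnm_stage(prefix = if (nzchar(parts[2])) parts[2] else NA_character_,
            t = parts[3], n = parts[4], m = parts[5])
}

#' Construct a TNM stage
#'
#' @param t,n,m component values from the closed vocabularies.
#' @param prefix optional `c`, `p` or `yp`.
#' @return a `tnm_stage`.
#' @export
tnm_stage <- function(t, n, m, prefix = NA_character_) {
  if (!is.na(prefix) && !prefix %in% TNM_PREFIXES)
    dw_stop("dw_value_error", sprintf("invalid TNM prefix '%s'", prefix))
  if (!t %in% TNM_T_VALUES)
    dw_stop("dw_value_error", sprintf("invalid T value '%s'", t))
  if (!n %in% TNM_N_VALUES)
    dw_stop("dw_value_error", sprintf("invalid N value '%s'", n))
  if (!m %in% TNM_M_VALUES)
    dw_stop("dw_value_error", sprintf("invalid M value '%s'", m))
  structure(list(prefix = prefix, t = t, n = n, m = m), class = "tnm_stage")
}

#' Serialize a TNM stage; round-trips through [extract_tnm()]
#'
#' @param stage a `tnm_stage`.
#' @return a string like `"pT2 N1 M0"`.
#' @export
format_tnm <- function(stage) {
  stopifnot(inherits(stage, "tnm_stage"))
  paste0(if (!is.na(stage$prefix)) stage$prefix else "",
         "T", stage$t, " N", stage$n, " M", stage$m)
}

#' @export
print.tnm_stage <- function(x, ...) {
  cat("<tnm_stage>", format_tnm(x), "\n")
  invisible(x)
}

#' Extract biomarker fields from diagnosis text
#'
#' Fills hormone receptors (percent, or qualitative positive/negative status
#' when no percent is given), Ki-67 percent, HER-2 immunohistochemistry score
#' (0/1+/2+/3+) and grade (G1-G3).  First mention of a field wins.  Percents
#' outside 0-100 raise a range error naming the field.
#'
#' @param text diagnosis-section text.
#' @param config an [extraction_config()].
#' @return named list of extracted values (`NA` where absent).
#' @export
extract_biomarkers <- function(text, config = extraction_config()) {
  fp <- config$field_patterns
  get_pct <- function(field) {
    raw <- first_capture(text, fp[[field]])
    if (is.na(raw)) return(NA_real_)
    val <- as.numeric(raw)
    if (val > 100)
      dw_stop("dw_range_error",
              sprintf("%s percent out of range: %s", field, raw),
              field = field)
    val
  }
  er <- get_pct("estrogens_receptors")
  pr <- get_pct("progesterone_receptors")
  er_status <- if (is.na(er))
    tolower(first_capture(text, fp$estrogens_receptors_status)) else NA_character_
  pr_status <- if (is.na(pr))
    tolower(first_capture(text, fp$progesterone_receptors_status)) else NA_character_
  list(estrogens_receptors = er,
       estrogens_receptors_status = er_status,
       progesterone_receptors = pr,
       progesterone_receptors_status = pr_status,
       ki67 = get_pct("ki67"),
       c_erb_b2 = as.integer(first_capture(text, fp$c_erb_b2)),
       grade = as.integer(first_capture(text, fp$grade)))
}

#' Run the full extraction pipeline on one report
#'
#' Sectionizes the report, reads the metadata preamble, then applies the
#' SNOMED, TNM and biomarker extractors to the coded diagnosis section only.
#' Pattern-shaped codes missing from the lexicon are dropped with a message.
#'
#' @param raw_text report text.
#' @param config an [extraction_config()].
#' @param report_id fallback id for error messages.
#' @return an [extraction_result()].
#' @export
extract_report <- function(raw_text, config = extraction_config(),
                           report_id = NULL) {
  doc <- sectionize(raw_text, config, report_id = report_id)
  diag <- doc$sections[[config$diagnosis_label]]
  rtype <- tolower(first_capture(doc$preamble, config$meta_patterns$type))
  rtype <- c(histological = "histological", istologico = "histological",
             cytological = "cytological", citologico = "cytological")[rtype]
  sn <- extract_snomed(diag, config$lexicon, config$snomed_pattern)
  if (length(sn$unknown))
    message(sprintf("report %s: dropping %d code(s) not in lexicon: %s",
                    doc$report_id, length(sn$unknown),
                    paste(sn$unknown, collapse = ", ")))
  bio <- extract_biomarkers(diag, config)
  extraction_result(
    name = doc$report_id,
    date = doc$report_date,
    type = unname(rtype),
    number = first_capture(doc$preamble, config$meta_patterns$number),
    estrogens_receptors = bio$estrogens_receptors,
    estrogens_receptors_status = bio$estrogens_receptors_status,
    progesterone_receptors = bio$progesterone_receptors,
    progesterone_receptors_status = bio$progesterone_receptors_status,
    ki67 = bio$ki67,
    c_erb_b2 = bio$c_erb_b2,
    grade = bio$grade,
    state = extract_tnm(diag),
    snomed = sn$matched)
}

#' Construct and validate a structured extraction result
#'
#' The structured record mirrors the XML output schema: report id, date and
#' type are required; specimen number, receptor values (percent or
#' qualitative status), Ki-67, HER-2 score, grade, TNM stage and the SNOMED
#' code list are optional.
#'
#' @param name anonymized report id.
#' @param date ISO-8601 report date.
#' @param type `"histological"` or `"cytological"`.
#' @param number specimen number string.
#' @param estrogens_receptors,progesterone_receptors percents in 0-100.
#' @param estrogens_receptors_status,progesterone_receptors_status qualitative
#'   `"positive"`/`"negative"`, mutually exclusive with the percent.
#' @param ki67 percent in 0-100.
#' @param c_erb_b2 integer score in 0-3.
#' @param grade integer 1-3.
#' @param state a [tnm_stage()] or `NULL`.
#' @param snomed data frame with columns `code`, `name`.
#' @param lexicon lexicon used to validate `snomed` codes; `NULL` skips the
#'   membership check.
#' @return a list of class `extraction_result`.
#' @export
extraction_result <- function(name, date, type, number = NA_character_,
                              estrogens_receptors = NA_real_,
                              estrogens_receptors_status = NA_character_,
                              progesterone_receptors = NA_real_,
                              progesterone_receptors_status = NA_character_,
                              ki67 = NA_real_, c_erb_b2 = NA_integer_,
                              grade = NA_integer_, state = NULL,
                              snomed = data.frame(code = character(0),
                                                  name = character(0),
                                                  stringsAsFactors = FALSE),
                              lexicon = NULL) {
  res <- structure(list(
    name = name, date = date, type = type, number = number,
    estrogens_receptors = as.numeric(estrogens_receptors),
    estrogens_receptors_status = estrogens_receptors_status,
    progesterone_receptors = as.numeric(progesterone_receptors),
    progesterone_receptors_status = progesterone_receptors_status,
    ki67 = as.numeric(ki67), c_erb_b2 = as.integer(c_erb_b2),
    grade = as.integer(grade), state = state,
    snomed = snomed), class = "extraction_result")
  validate_extraction_result(res, lexicon = lexicon)
  res
}

#' Validate an extraction result against its invariants
#'
#' @param res an `extraction_result`.
#' @param lexicon optional lexicon for SNOMED membership checking.
#' @return `res`, invisibly; invalid records raise a validation error listing
#'   every failing field.
#' @export
validate_extraction_result <- function(res, lexicon = NULL) {
  bad <- character(0)
  if (is.na(res$name) || !nzchar(res$name)) bad <- c(bad, "name")
  if (is.na(res$date) || !is_iso_date(res$date)) bad <- c(bad, "date")
  if (is.na(res$type) || !res$type %in% c("histological", "cytological"))
    bad <- c(bad, "type")
  pct_ok <- function(x) is.na(x) || (x >= 0 && x <= 100)
  if (!pct_ok(res$estrogens_receptors)) bad <- c(bad, "estrogens_receptors")
  if (!pct_ok(res$progesterone_receptors))
    bad <- c(bad, "progesterone_receptors")
  if (!pct_ok(res$ki67)) bad <- c(bad, "ki67")
  st_ok <- function(x) is.na(x) || x %in% c("positive", "negative")
  if (!st_ok(res$estrogens_receptors_status))
    bad <- c(bad, "estrogens_receptors_status")
  if (!st_ok(res$progesterone_receptors_status))
    bad <- c(bad, "progesterone_receptors_status")
  if (!is.na(res$estrogens_receptors) &&
      !is.na(res$estrogens_receptors_status))
    bad <- c(bad, "estrogens_receptors_status")
  if (!is.na(res$progesterone_receptors) &&
      !is.na(res$progesterone_receptors_status))
    bad <- c(bad, "progesterone_receptors_status")
  if (!is.na(res$c_erb_b2) && !res$c_erb_b2 %in% 0:3) bad <- c(bad, "c_erb_b2")
  if (!is.na(res$grade) && !res$grade %in% 1:3) bad <- c(bad, "grade")
  if (!is.null(res$state) && !inherits(res$state, "tnm_stage"))
    bad <- c(bad, "state")
  if (!is.data.frame(res$snomed) ||
      !all(c("code", "name") %in% names(res$snomed)))
    bad <- c(bad, "snomed")
  else if (!is.null(lexicon) && nrow(res$snomed) &&
           !all(res$snomed$code %in% names(lexicon)))
    bad <- c(bad, "snomed")
  if (length(bad))
    dw_stop("dw_validation_error",
            sprintf("invalid extraction result (fields: %s)",
                    paste(unique(bad), collapse = ", ")),
            fields = unique(bad))
  invisible(res)
}

#' @export
print.extraction_result <- function(x, ...) {
  cat(sprintf("<extraction_result> %s (%s, %s)\n", x$name, x$date, x$type))
  if (nrow(x$snomed))
    cat("  snomed:", paste(x$snomed$code, collapse = " "), "\n")
  if (!is.null(x$state)) cat("  TNM:", format_tnm(x$state), "\n")
  invisible(x)
}

#' Extract a directory of report files in batch
#'
#' @param reports_dir directory of one-report-per-file UTF-8 text files.
#' @param config an [extraction_config()].
#' @param out_dir optional directory; when given, one XML file per report and
#'   a tab-separated `manifest.tsv` (report file, xml file, status) are
#'   written there.
#' @return list of [extraction_result()]s, named by report id.
#' @export
extract_batch <- function(reports_dir, config = extraction_config(),
                          out_dir = NULL) {
  files <- sort(list.files(reports_dir, pattern = "\\.txt$",
                           full.names = TRUE))
  results <- list()
  manifest <- list()
  for (f in files) {
    txt <- paste(readLines(f, encoding = "UTF-8", warn = FALSE),
                 collapse = "\n")
    res <- extract_report(txt, config, report_id = basename(f))
    results[[res$name]] <- res
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      xf <- file.path(out_dir, paste0(res$name, ".xml"))
      write_extraction_xml(res, xf)
      manifest[[length(manifest) + 1]] <-
        data.frame(report_file = basename(f), xml_file = basename(xf),
                   status = "ok", stringsAsFactors = FALSE)
    }
  }
  if (!is.null(out_dir) && length(manifest))
    dw_write_table(do.call(rbind, manifest),
                   file.path(out_dir, "manifest.tsv"))
  results
}
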