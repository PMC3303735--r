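## Seedable generator of a mock hospital ecosystem: patients with visits and
## survival outcomes, pathology reports rendered as sectioned text with a
## known structured ground truth, and a biobanked subset with specimens
## awaiting sync.  The defaults mirror the cohort the platform was built
## around: a breast-cancer population collected over 2001-2011 in which
## roughly 5.9% of patients (393/6713) have at least one biobanked sample.
## All randomness flows from one seeded stream; the same seed reproduces the
## outputs byte for byte.  Donor names exist only so that the anonymization
## layer has something to protect: they are syllable-generated and filtered
## against the package's export vocabulary, so any identifier substring found
## in a warehouse or biobank export is a genuine leak, not a lexical
## coincidence.

#' Cohort generator parameters
#'
#' @param n_patients number of patients to simulate.
#' @param biobank_fraction probability a patient has biobanked samples;
#'   default 393/6713.
#' @param date_window two ISO dates bounding visits and reports.
#' @param noise_level `"none"` (canonical templates), `"light"` (header
#'   aliases, case, spacing and label variants; coded tokens untouched) or
#'   `"heavy"` (light noise plus randomly omitted optional fields).
#' @param seed integer seed.
#' @return a `cohort_params` list.
#' @export
cohort_params <- function(n_patients, biobank_fraction = 393 / 6713,
                          date_window = c("2001-01-01", "2011-12-31"),
                          noise_level = c("none", "light", "heavy"),
                          seed = 1L) {
  noise_level <- match.arg(noise_level)
  stopifnot(n_patients >= 1, biobank_fraction >= 0, biobank_fraction <= 1,
            length(date_window) == 2)
  if (!date_le(date_window[1], date_window[2]) ||
      date_window[1] == date_window[2])
    dw_stop("dw_value_error", "date_window start must precede end")
  structure(list(n_patients = as.integer(n_patients),
                 biobank_fraction = biobank_fraction,
                 date_window = date_window, noise_level = noise_level,
                 seed = as.integer(seed)), class = "cohort_params")
}

SAMPLE_DESCRIPTIONS <- c("FFPE block from surgical resection",
                         "Frozen aliquot stored at minus eighty",
                         "Formalin fixed specimen",
                         "Cryopreserved aliquot")
VISIT_LOCATIONS <- c("ONC-WARD", "DAY-HOSP", "SURGERY")

#' Every string that may legitimately appear in a warehouse or biobank export
#'
#' Used by the name generator to guarantee that synthetic donor identifiers
#' share no length-4 substring with regular export content.
#'
#' @return character vector.
#' @export
export_vocabulary <- function() {
  cd <- build_concept_dimension()
  unique(c(cd$concept_code, cd$concept_path, cd$name, cd$source,
           names(PATIENT_COLS), names(VISIT_COLS), names(PROVIDER_COLS),
           names(CONCEPT_COLS), names(FACT_COLS), names(BIOBANK_COLS),
           MATERIAL_TYPES, BIOBANK_PROJECTS, SAMPLE_TYPES,
           SAMPLE_DESCRIPTIONS, VISIT_LOCATIONS,
           default_providers()$name, default_providers()$department,
           "histological", "cytological", "positive", "negative",
           "numeric", "text", "none", "alive", "deceased", "unknown",
           "TRUE", "FALSE", BARCODE_PREFIX))
}

ngrams4 <- function(strings) {
  unique(unlist(lapply(toupper(strings), function(s) {
    n <- nchar(s)
    if (is.na(s) || n < 4) return(character(0))
    vapply(seq_len(n - 3L), function(i) substring(s, i, i + 3L), character(1))
  })))
}

NAME_SYLLABLES <- c("ba", "be", "bi", "bo", "da", "de", "di", "do", "fa",
                    "fe", "ga", "gi", "ka", "ke", "la", "le", "li", "lo",
                    "ma", "me", "mi", "mo", "na", "ne", "ni", "no", "pa",
                    "pe", "ra", "re", "ri", "ro", "sa", "se", "si", "so",
                    "ta", "te", "ti", "to", "va", "ve", "vi", "za", "zo")

gen_name <- function(n_syllables, vocab_grams) {
  repeat {
    nm <- paste(sample(NAME_SYLLABLES, n_syllables, replace = TRUE),
                collapse = "")
    nm <- paste0(toupper(substring(nm, 1, 1)), substring(nm, 2))
    if (!any(ngrams4(nm) %in% vocab_grams)) return(nm)
  }
}

sample1 <- function(x, ...) x[sample.int(length(x), 1, ...)]

## ---- report rendering -------------------------------------------------------

HEADER_SETS <- list(
  c(an = "ANAMNESIS", mac = "MACROSCOPIC DESCRIPTION", diag = "DIAGNOSIS"),
  c(an = "Anamnesis", mac = "Macroscopic description", diag = "Diagnosis"),
  c(an = "ANAMNESI", mac = "DESCRIZIONE MACROSCOPICA", diag = "DIAGNOSI"),
  c(an = "CLINICAL HISTORY", mac = "GROSS DESCRIPTION",
    diag = "CODED DIAGNOSIS"))

ANAMNESIS_FILLER <- c(
  "Patient referred from the oncology day hospital after screening mammography.",
  "Palpable nodule of the left breast, first noticed three months ago.",
  "Follow up after neoadjuvant chemotherapy, clinical response reported.",
  "Family history of breast disease reported at admission.")

MACRO_FILLER <- c(
  "Lumpectomy specimen measuring 45 x 30 x 20 mm, single nodular lesion.",
  "Core biopsy, three fragments of whitish tissue up to 15 mm.",
  "Mastectomy specimen with retracted skin flap, lesion in upper outer quadrant.",
  "Wide excision specimen, firm greyish area on the cut surface.")

#' Render a ground-truth report record as sectioned text
#'
#' All coded values are placed only in the diagnosis section; the anamnesis
#' may carry decoy mentions (an in-lexicon code and a Ki-67 percent that
#' differ from the truth), which a section-restricted extractor must ignore.
#' At `noise_level = "none"` the canonical template is used; `"light"`
#' perturbs headers, label spellings, date format and spacing but never the
#' coded tokens; `"heavy"` additionally drops optional fields at random.
#'
#' @param rec a ground-truth report record (see [simulate_cohort()]).
#' @param noise_level `"none"`, `"light"` or `"heavy"`.
#' @param lexicon code lexicon, for decoy selection.
#' @return list with `text` and `dropped` (field names omitted from the
#'   rendering).
#' @export
render_report <- function(rec, noise_level = "none",
                          lexicon = snomed_lexicon()) {
  noisy <- noise_level %in% c("light", "heavy")
  hs <- if (noisy) HEADER_SETS[[sample.int(length(HEADER_SETS), 1)]]
        else HEADER_SETS[[1]]
  dropped <- character(0)
  if (noise_level == "heavy") {
    droppable <- c("state", "grade", "estrogens_receptors",
                   "progesterone_receptors", "ki67", "c_erb_b2", "number")
    present <- vapply(droppable, function(f) {
      if (f == "state") !is.null(rec$state)
      else !is.na(rec[[f]]) ||
        (f %in% c("estrogens_receptors", "progesterone_receptors") &&
           !is.na(rec[[paste0(f, "_status")]]))
    }, logical(1))
    dropped <- droppable[present & runif(length(droppable)) < 0.15]
  }
  has <- function(f) !(f %in% dropped)
  date_str <- if (noisy && runif(1) < 0.5)
    format(as.Date(rec$date), "%d/%m/%Y") else rec$date
  pre <- c(paste0("REPORT ID: ", rec$name),
           paste0("REPORT DATE: ", date_str),
           paste0("REPORT TYPE: ", toupper(rec$type)))
  if (!is.na(rec$number) && has("number"))
    pre <- c(pre, paste0("SPECIMEN NUMBER: ", rec$number))

  an <- sample1(ANAMNESIS_FILLER)
  if (runif(1) < 0.5) {
    decoy_code <- sample1(setdiff(names(lexicon), rec$snomed$code))
    decoy_ki <- if (!is.na(rec$ki67) && rec$ki67 == 70) 65 else 70
    an <- c(an, sprintf(
      "An earlier specimen reviewed elsewhere was coded %s with Ki-67 %d%% and stage pT4 N3 M1.",
      decoy_code, decoy_ki))
  }

  lab <- function(variants) if (noisy) sample1(variants) else variants[1]
  diag <- sprintf("%s (%s).", rec$snomed$name, rec$snomed$code)
  if (!is.null(rec$state) && has("state"))
    diag <- c(diag, paste0(lab(c("TNM stage: ", "Stage: ")),
                           format_tnm(rec$state), "."))
  if (!is.na(rec$grade) && has("grade"))
    diag <- c(diag, if (noisy && runif(1) < 0.3)
      sprintf("Histologic grade G%d.", rec$grade)
      else sprintf("Grade: G%d.", rec$grade))
  fmt_receptor <- function(value, status, variants) {
    if (!is.na(value)) sprintf("%s: %d%%.", lab(variants), value)
    else if (!is.na(status)) sprintf("%s: %s.", lab(variants), status)
    else NULL
  }
  if (has("estrogens_receptors"))
    diag <- c(diag, fmt_receptor(rec$estrogens_receptors,
                                 rec$estrogens_receptors_status,
                                 c("Estrogen receptors", "ER")))
  if (has("progesterone_receptors"))
    diag <- c(diag, fmt_receptor(rec$progesterone_receptors,
                                 rec$progesterone_receptors_status,
                                 c("Progesterone receptors", "PgR", "PR")))
  if (!is.na(rec$ki67) && has("ki67"))
    diag <- c(diag, sprintf("%s: %d%%.", lab(c("Ki-67", "Ki67")),
                            rec$ki67))
  if (!is.na(rec$c_erb_b2) && has("c_erb_b2"))
    diag <- c(diag, sprintf("%s: %d+.",
                            lab(c("c-erbB2 (DAKO)", "HER-2")),
                            rec$c_erb_b2))

  gap <- function() if (noisy && runif(1) < 0.3) c("", "") else ""
  text <- paste(c(pre, gap(),
                  paste0(hs[["an"]], ":"), an, gap(),
                  paste0(hs[["mac"]], ":"), sample1(MACRO_FILLER), gap(),
                  paste0(hs[["diag"]], ":"), diag),
                collapse = "\n")
  list(text = text, dropped = dropped)
}

## ---- cohort simulation ------------------------------------------------------

#' Simulate a full mock hospital ecosystem
#'
#' Produces, deterministically for a given seed: the pathology-unit specimen
#' table (with donor identifier fields, which exist only to exercise the
#' anonymization layer), the report-to-patient map, the HIS patient and
#' visit tables, rendered report texts, and a `truth` component holding the
#' per-report structured records, per-patient survival, the biobank flags
#' and the expected warehouse tallies.
#'
#' Distributions: ER/PR percents have a point mass at 0 and are otherwise
#' uniform on 1-100 (a minority are recorded qualitatively as
#' positive/negative); Ki-67 is a uniform-ish percent; HER-2 scores range
#' over 0-3; TNM components are drawn from their closed vocabularies; SNOMED
#' codes come from the packaged lexicon; the biobanked subset is
#' Binomial(n, biobank_fraction).
#'
#' @param params a [cohort_params()].
#' @return a list of class `cohort_sim`; see Details.
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  with_seed(params$seed, simulate_cohort_impl(params))
}

simulate_cohort_impl <- function(params) {
  lex <- snomed_lexicon()
  lex_codes <- setdiff(names(lex), "M-80000")  # the root term is not a finding
  vocab_grams <- ngrams4(export_vocabulary())
  w0 <- as.Date(params$date_window[1])
  w1 <- as.Date(params$date_window[2])
  span <- as.numeric(w1 - w0)

  patients <- list(); visits <- list(); reports <- list()
  report_map <- list(); specimens <- list(); survival <- list()
  texts <- character(0)
  report_counter <- 0L
  specimen_counter <- 0L

  for (i in seq_len(params$n_patients)) {
    pu_id <- sprintf("MRN-%06d", i)
    given <- gen_name(sample(2:3, 1), vocab_grams)
    family <- gen_name(sample(2:4, 1), vocab_grams)
    sex <- sample1(c("F", "M"), prob = c(0.98, 0.02))
    birth <- as_iso_date(as.Date("1925-01-01") + sample.int(18250, 1))

    n_visits <- sample.int(5, 1)
    starts <- sort(sample.int(span - 30L, n_visits)) + w0
    ends <- starts + sample.int(4, n_visits, replace = TRUE) - 1L
    vids <- sprintf("V-%06d-%d", i, seq_len(n_visits))
    visits[[i]] <- data.frame(visit_id = vids, pu_patient_id = pu_id,
                              start_date = as_iso_date(starts),
                              end_date = as_iso_date(ends),
                              location_code = vapply(seq_len(n_visits),
                                function(k) sample1(VISIT_LOCATIONS),
                                character(1)),
                              stringsAsFactors = FALSE)

    deceased <- runif(1) < 0.18
    death <- if (deceased)
      as_iso_date(max(ends) + sample(30:1500, 1)) else NA_character_
    patients[[i]] <- data.frame(
      pu_patient_id = pu_id, sex = sex, birth_date = birth,
      vital_status = if (deceased) "deceased" else "alive",
      death_date = death, given_name = given, family_name = family,
      stringsAsFactors = FALSE)

    n_reports <- if (n_visits >= 2 && runif(1) < 0.3) 2L else 1L
    pat_reports <- list()
    for (r in seq_len(n_reports)) {
      report_counter <- report_counter + 1L
      rid <- sprintf("RPT-%06d", report_counter)
      rdate <- as_iso_date(starts[r])
      type <- sample1(c("histological", "cytological"), prob = c(0.8, 0.2))
      codes <- sample(lex_codes, sample.int(3, 1))
      state <- if (type == "histological" && runif(1) < 0.9)
        tnm_stage(t = sample1(TNM_T_VALUES), n = sample1(TNM_N_VALUES),
                  m = sample1(TNM_M_VALUES),
                  prefix = sample1(c("p", "c", "yp", NA_character_),
                                   prob = c(0.65, 0.2, 0.05, 0.1)))
      else NULL
      draw_receptor <- function() {
        if (runif(1) >= 0.9)
          return(list(value = NA_real_, status = NA_character_))
        if (runif(1) < 0.15)
          list(value = NA_real_,
               status = sample1(c("positive", "negative")))
        else list(value = if (runif(1) < 0.25) 0
                  else sample.int(100, 1), status = NA_character_)
      }
      er <- draw_receptor(); pr <- draw_receptor()
      rec <- extraction_result(
        name = rid, date = rdate, type = type,
        number = sprintf("S-%s/%04d", substr(rdate, 1, 4), report_counter),
        estrogens_receptors = er$value,
        estrogens_receptors_status = er$status,
        progesterone_receptors = pr$value,
        progesterone_receptors_status = pr$status,
        ki67 = if (runif(1) < 0.9) sample.int(80, 1) else NA_real_,
        c_erb_b2 = if (runif(1) < 0.85)
          sample(0:3, 1, prob = c(0.3, 0.3, 0.25, 0.15)) else NA_integer_,
        grade = if (runif(1) < 0.85) sample.int(3, 1) else NA_integer_,
        state = state,
        snomed = data.frame(code = codes, name = unname(lex[codes]),
                            stringsAsFactors = FALSE))
      rendered <- render_report(rec, params$noise_level, lex)
      texts[[rid]] <- rendered$text
      pat_reports[[r]] <- list(record = rec, dropped = rendered$dropped,
                               pu_patient_id = pu_id)
      report_map[[length(report_map) + 1]] <-
        data.frame(report_id = rid, pu_patient_id = pu_id,
                   stringsAsFactors = FALSE)
    }
    reports <- c(reports, pat_reports)

    index_date <- as.Date(as_iso_date(starts[1]))
    survival[[i]] <- data.frame(
      pu_patient_id = pu_id,
      time = if (deceased) as.numeric(as.Date(death) - index_date)
             else as.numeric(max(ends) - index_date),
      event = deceased, stringsAsFactors = FALSE)

    biobanked <- runif(1) < params$biobank_fraction
    if (biobanked) {
      n_samples <- sample.int(3, 1)
      for (s in seq_len(n_samples)) {
        specimen_counter <- specimen_counter + 1L
        cdate <- as_iso_date(starts[1] + sample.int(11, 1) - 1L)
        specimens[[length(specimens) + 1]] <- data.frame(
          pu_specimen_id = sprintf("SPC-%06d", specimen_counter),
          pu_patient_id = pu_id,
          material_type = sample1(MATERIAL_TYPES,
                                  prob = c(0.45, 0.2, 0.1, 0.1, 0.06, 0.04,
                                           0.05)),
          fridge_position = sprintf("FR%d-S%d-B%02d", sample.int(6, 1),
                                    sample.int(8, 1), sample.int(99, 1)),
          consent_research = runif(1) < 0.92,
          project = sample1(BIOBANK_PROJECTS),
          sample_type = sample1(SAMPLE_TYPES),
          creation_date = cdate,
          description = sample1(SAMPLE_DESCRIPTIONS),
          updated_at = paste0(cdate, "T", sprintf("%02d:%02d:00",
                              sample(8:21, 1), sample(0:59, 1))),
          given_name = given, family_name = family,
          stringsAsFactors = FALSE)
      }
    }
  }

  patients <- do.call(rbind, patients)
  visits <- do.call(rbind, visits)
  specimens <- if (length(specimens)) do.call(rbind, specimens)
    else empty_df(c(pu_specimen_id = "character", pu_patient_id = "character",
                    material_type = "character",
                    fridge_position = "character",
                    consent_research = "logical", project = "character",
                    sample_type = "character", creation_date = "character",
                    description = "character", updated_at = "character",
                    given_name = "character", family_name = "character"))
  report_map <- do.call(rbind, report_map)
  survival <- do.call(rbind, survival)

  truth <- list(patients = patients, reports = reports,
                specimens = specimens, survival = survival,
                biobanked_patients = unique(
                  specimens$pu_patient_id[isTRUE_v(specimens$consent_research)]))
  truth$tallies <- ground_truth_tallies(params, patients, visits, reports,
                                        specimens)
  structure(list(params = params,
                 pu_specimens = specimens,
                 report_map = report_map,
                 his = list(
                   patients = patients[, c("pu_patient_id", "sex",
                                           "birth_date", "vital_status",
                                           "death_date")],
                   visits = visits),
                 report_texts = texts,
                 truth = truth), class = "cohort_sim")
}

isTRUE_v <- function(x) !is.na(x) & x

## Expected warehouse tallies, computed by direct arithmetic over the ground
## truth (never by running the ETL), so conservation tests compare two
## independent routes.  Valid for noise_level "none"/"light"; at "heavy",
## dropped fields are excluded because they are absent from the rendered
## text and hence from any faithful extraction.
ground_truth_tallies <- function(params, patients, visits, reports,
                                 specimens) {
  demo_facts <- 2L * nrow(patients)
  report_facts <- sum(vapply(reports, function(rp) {
    rec <- rp$record
    d <- rp$dropped
    has <- function(f) !(f %in% d)
    nrow(rec$snomed) +
      3L * (!is.null(rec$state) && has("state")) +
      (!is.na(rec$grade) && has("grade")) +
      ((!is.na(rec$estrogens_receptors) ||
          !is.na(rec$estrogens_receptors_status)) &&
         has("estrogens_receptors")) +
      ((!is.na(rec$progesterone_receptors) ||
          !is.na(rec$progesterone_receptors_status)) &&
         has("progesterone_receptors")) +
      (!is.na(rec$ki67) && has("ki67")) +
      (!is.na(rec$c_erb_b2) && has("c_erb_b2"))
  }, numeric(1)))
  consented <- if (nrow(specimens))
    specimens[isTRUE_v(specimens$consent_research), , drop = FALSE]
  else specimens
  sample_facts <- 3L * nrow(consented)
  list(n_patients = nrow(patients),
       n_visits = nrow(visits),
       n_facts = as.integer(demo_facts + report_facts + sample_facts),
       n_concepts = nrow(build_concept_dimension()),
       n_biobanked_patients = length(unique(consented$pu_patient_id)))
}

#' Write the simulated sources to disk
#'
#' Writes the PU specimen table, the report map, the HIS tables, one report
#' text file per report under `reports/`, and a `manifest.tsv` listing every
#' artifact with its MD5 checksum.  Ground truth stays in memory; it is the
#' test harness's property, not a source system.
#'
#' @param sim a [simulate_cohort()] result.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "cohort_sim"))
  dir.create(file.path(dir, "reports"), recursive = TRUE,
             showWarnings = FALSE)
  dw_write_table(sim$pu_specimens, file.path(dir, "pu_specimens.tsv"))
  dw_write_table(sim$report_map, file.path(dir, "report_map.tsv"))
  dw_write_table(sim$his$patients, file.path(dir, "his_patients.tsv"))
  dw_write_table(sim$his$visits, file.path(dir, "his_visits.tsv"))
  for (rid in names(sim$report_texts))
    writeLines(sim$report_texts[[rid]],
               file.path(dir, "reports", paste0(rid, ".txt")),
               useBytes = TRUE)
  files <- setdiff(list.files(dir, recursive = TRUE), "manifest.tsv")
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(dir, files))),
                         stringsAsFactors = FALSE)
  dw_write_table(manifest, file.path(dir, "manifest.tsv"))
  invisible(dir)
}

#' Read back the sources written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return list with `pu_specimens`, `report_map`, `his`, `report_texts`.
#' @export
read_cohort <- function(dir) {
  texts <- list()
  for (f in sort(list.files(file.path(dir, "reports"), full.names = TRUE)))
    texts[[sub("\\.txt$", "", basename(f))]] <-
      paste(readLines(f, encoding = "UTF-8", warn = FALSE), collapse = "\n")
  list(pu_specimens = dw_read_table(file.path(dir, "pu_specimens.tsv"),
                                    logical_cols = "consent_research"),
       report_map = dw_read_table(file.path(dir, "report_map.tsv")),
       his = list(patients = {
         p <- dw_read_table(file.path(dir, "his_patients.tsv"))
         p$death_date <- ifelse(p$death_date == "", NA_character_,
                                p$death_date)
         p
       },
       visits = dw_read_table(file.path(dir, "his_visits.tsv"))),
       report_texts = texts)
}
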