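## Shared fixtures and independent oracles.  The oracles deliberately avoid
## the package's own path/constraint machinery so that equivalence tests
## compare two routes to the same answer.

## Run the whole pipeline (simulate -> extract -> sync -> load) in memory.
run_pipeline <- function(n, seed, noise = "none", sync_seed = seed + 1000L) {
  sim <- simulate_cohort(cohort_params(n, seed = seed, noise_level = noise))
  cfgx <- extraction_config()
  extractions <- unname(lapply(sim$report_texts, extract_report,
                               config = cfgx))
  set.seed(sync_seed)
  sy <- sync_pu_to_biobank(sim$pu_specimens, new_biobank(), new_lookup(),
                           new_sync_state())
  out <- load_warehouse(new_warehouse(), build_concept_dimension(), sim$his,
                        extractions, sy$biobank, sy$lookup, sim$report_map)
  list(sim = sim, extractions = extractions, sync = sy,
       warehouse = out$warehouse, lookup = out$lookup, report = out$report)
}

## Independent segment-level prefix test (no startsWith on raw strings).
oracle_segments <- function(path) {
  s <- strsplit(path, "\\", fixed = TRUE)[[1]]
  s[nzchar(s)]
}

oracle_is_under <- function(path, prefix) {
  ps <- oracle_segments(path)
  qs <- oracle_segments(prefix)
  length(ps) >= length(qs) && identical(ps[seq_along(qs)], qs)
}

## Brute-force panel evaluation straight off the fact table.
oracle_eval_panel <- function(panel, wh, concepts) {
  codes <- character(0)
  for (item in panel$items)
    for (i in seq_len(nrow(concepts)))
      if (oracle_is_under(concepts$concept_path[i], item))
        codes <- c(codes, concepts$concept_code[i])
  codes <- unique(codes)
  f <- wh$facts
  ids <- character(0)
  for (i in seq_len(nrow(f))) {
    if (!f$concept_code[i] %in% codes) next
    if (!is.null(panel$date_from) &&
        as.Date(f$obs_date[i]) < as.Date(panel$date_from)) next
    if (!is.null(panel$date_to) &&
        as.Date(f$obs_date[i]) > as.Date(panel$date_to)) next
    if (!is.null(panel$value_op)) {
      if (f$value_type[i] != "numeric") next
      v <- f$numeric_value[i]
      ok <- switch(panel$value_op,
                   ">=" = v >= panel$value,
                   "<=" = v <= panel$value,
                   "=" = v == panel$value,
                   "between" = v >= panel$value && v <= panel$value2)
      if (!ok) next
    }
    ids <- c(ids, f$patient_id[i])
  }
  ids <- unique(ids)
  if (panel$invert) setdiff(wh$patients$patient_id, ids) else ids
}

oracle_run_query <- function(def, wh, concepts) {
  sets <- lapply(def$panels, oracle_eval_panel, wh = wh, concepts = concepts)
  sort(Reduce(intersect, sets))
}

## Random but well-formed query definitions.  Value constraints are drawn
## only over biomarker leaves, where numeric facts live.
BIOMARKER_PATHS <- c("\\Biomarkers\\Ki-67\\", "\\Biomarkers\\Grade\\",
                     "\\Biomarkers\\Estrogen receptors\\",
                     "\\Biomarkers\\Progesterone receptors\\",
                     "\\Biomarkers\\HER-2 score\\")

random_query_definition <- function(concepts) {
  n_panels <- sample.int(3, 1)
  panels <- lapply(seq_len(n_panels), function(k) {
    if (runif(1) < 0.35) {
      lo <- sample(0:60, 1)
      op <- sample(c(">=", "<=", "=", "between"), 1)
      query_panel(sample(BIOMARKER_PATHS, sample.int(2, 1)),
                  value_op = op, value = lo,
                  value2 = if (op == "between") lo + sample(0:40, 1),
                  invert = runif(1) < 0.1)
    } else {
      items <- sample(concepts$concept_path, sample.int(3, 1))
      df <- dt <- NULL
      if (runif(1) < 0.3) {
        d0 <- as.Date("2001-01-01") + sample.int(3500, 1)
        df <- format(d0, "%Y-%m-%d")
        dt <- format(d0 + sample.int(2000, 1), "%Y-%m-%d")
      }
      query_panel(items, date_from = df, date_to = dt,
                  invert = runif(1) < 0.15)
    }
  })
  query_definition(panels)
}

## Random valid extraction results, independent of the cohort generator.
random_extraction_result <- function(lex = snomed_lexicon()) {
  maybe <- function(p, expr) if (runif(1) < p) expr else NULL
  er_num <- maybe(0.5, sample(0:100, 1))
  er_st <- if (is.null(er_num)) maybe(0.4, sample(c("positive", "negative"), 1))
  pr_num <- maybe(0.5, sample(0:100, 1))
  pr_st <- if (is.null(pr_num)) maybe(0.4, sample(c("positive", "negative"), 1))
  k <- sample(0:4, 1)
  codes <- if (k > 0) sample(names(lex), k) else character(0)
  extraction_result(
    name = sprintf("RPT-%06d", sample.int(999999, 1)),
    date = format(as.Date("2001-01-01") + sample.int(4000, 1), "%Y-%m-%d"),
    type = sample(c("histological", "cytological"), 1),
    number = if (runif(1) < 0.8) sprintf("S-%04d", sample.int(9999, 1))
             else NA_character_,
    estrogens_receptors = er_num %||% NA_real_,
    estrogens_receptors_status = er_st %||% NA_character_,
    progesterone_receptors = pr_num %||% NA_real_,
    progesterone_receptors_status = pr_st %||% NA_character_,
    ki67 = if (runif(1) < 0.8) sample(0:100, 1) else NA_real_,
    c_erb_b2 = if (runif(1) < 0.7) sample(0:3, 1) else NA_integer_,
    grade = if (runif(1) < 0.7) sample(1:3, 1) else NA_integer_,
    state = if (runif(1) < 0.7)
      tnm_stage(t = sample(oncodw:::TNM_T_VALUES, 1),
                n = sample(oncodw:::TNM_N_VALUES, 1),
                m = sample(oncodw:::TNM_M_VALUES, 1),
                prefix = sample(c("c", "p", "yp", NA_character_), 1)),
    snomed = data.frame(code = codes, name = unname(lex[codes]),
                        stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

expect_same_result <- function(a, b) {
  expect_identical(a$name, b$name)
  expect_identical(a$date, b$date)
  expect_identical(a$type, b$type)
  expect_identical(a$number, b$number)
  expect_equal(a$estrogens_receptors, b$estrogens_receptors)
  expect_identical(a$estrogens_receptors_status, b$estrogens_receptors_status)
  expect_equal(a$progesterone_receptors, b$progesterone_receptors)
  expect_identical(a$progesterone_receptors_status,
                   b$progesterone_receptors_status)
  expect_equal(a$ki67, b$ki67)
  expect_equal(a$c_erb_b2, b$c_erb_b2)
  expect_equal(a$grade, b$grade)
  fmt <- function(s) if (is.null(s)) "" else format_tnm(s)
  expect_identical(fmt(a$state), fmt(b$state))
  expect_identical(a$snomed$code, b$snomed$code)
  expect_identical(a$snomed$name, b$snomed$name)
}

## Count per-field extraction agreement between ground truth and extraction.
field_accuracy <- function(truth_reports, texts, config) {
  total <- 0L
  correct <- 0L
  scalar_fields <- c("name", "date", "type", "number",
                     "estrogens_receptors", "estrogens_receptors_status",
                     "progesterone_receptors", "progesterone_receptors_status",
                     "ki67", "c_erb_b2", "grade")
  for (rp in truth_reports) {
    tr <- rp$record
    got <- extract_report(texts[[tr$name]], config)
    for (f in scalar_fields) {
      if (is.na(tr[[f]])) next
      total <- total + 1L
      if (!is.na(got[[f]]) && got[[f]] == tr[[f]])
        correct <- correct + 1L
    }
    if (!is.null(tr$state)) {
      total <- total + 1L
      if (!is.null(got$state) &&
          identical(format_tnm(got$state), format_tnm(tr$state)))
        correct <- correct + 1L
    }
    if (nrow(tr$snomed)) {
      total <- total + 1L
      if (identical(got$snomed$code, tr$snomed$code))
        correct <- correct + 1L
    }
  }
  list(total = total, correct = correct,
       accuracy_pct = 100 * correct / total)
}
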