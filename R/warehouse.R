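## Star-schema warehouse: a central observation-fact table and four dimension
## tables (patients, visits, providers, medical concepts), the layout used by
## i2b2-style clinical research charts.  Concept hierarchy is encoded in
## backslash-delimited path strings with leading and trailing delimiter;
## `level` counts path segments, so "\SNOMED\Neoplasm\" has level 2.

PATIENT_COLS  <- c(patient_id = "character", sex = "character",
                   birth_date = "character", vital_status = "character",
                   death_date = "character")
VISIT_COLS    <- c(visit_id = "character", patient_id = "character",
                   start_date = "character", end_date = "character",
                   location_code = "character")
PROVIDER_COLS <- c(provider_id = "character", name = "character",
                   department = "character")
CONCEPT_COLS  <- c(concept_code = "character", concept_path = "character",
                   name = "character", level = "integer", source = "character")
FACT_COLS     <- c(patient_id = "character", visit_id = "character",
                   concept_code = "character", provider_id = "character",
                   obs_date = "character", value_type = "character",
                   numeric_value = "numeric", text_value = "character",
                   units = "character", instance_num = "integer")

CONCEPT_SOURCES <- c("SNOMED", "TNM", "BIOMARKER", "BIOBANK", "DEMOGRAPHIC",
                     "VISIT", "OTHER")

#' Create an empty star-schema warehouse
#'
#' The warehouse holds five tables: `patients`, `visits`, `providers`,
#' `concepts` (the queryable ontology, one row per concept path) and `facts`
#' (one coded observation about a patient at a visit).  The unique key of a
#' fact is (patient_id, visit_id, concept_code, obs_date, instance_num);
#' re-inserting an existing key replaces the stored row.
#'
#' @return an object of class `warehouse`.
#' @seealso [upsert_fact()], [integrity_check()], [warehouse_counts()]
#' @export
new_warehouse <- function() {
  structure(list(patients  = empty_df(PATIENT_COLS),
                 visits    = empty_df(VISIT_COLS),
                 providers = empty_df(PROVIDER_COLS),
                 concepts  = empty_df(CONCEPT_COLS),
                 facts     = empty_df(FACT_COLS)),
            class = "warehouse")
}

#' @export
print.warehouse <- function(x, ...) {
  cat("<warehouse>", sprintf("%d facts | %d patients | %d visits | %d concepts | %d providers\n",
      nrow(x$facts), nrow(x$patients), nrow(x$visits), nrow(x$concepts),
      nrow(x$providers)))
  invisible(x)
}

## ---- concept-path helpers ---------------------------------------------------

path_segments <- function(path) {
  segs <- strsplit(path, "\\", fixed = TRUE)[[1]]
  segs[nzchar(segs)]
}

path_level <- function(path) {
  vapply(strsplit(path, "\\", fixed = TRUE),
         function(s) sum(nzchar(s)), integer(1))
}

#' @noRd
## Segment-aligned prefix: both arguments carry leading and trailing
## backslashes, so plain startsWith never matches a partial segment
## ("\A\BC\" is not under "\A\B\").
path_has_prefix <- function(path, prefix) startsWith(path, prefix)

parent_path <- function(path) {
  segs <- strsplit(path, "\\", fixed = TRUE)
  vapply(segs, function(s) {
    s <- s[nzchar(s)]
    if (length(s) <= 1) NA_character_
    else paste0("\\", paste(s[-length(s)], collapse = "\\"), "\\")
  }, character(1))
}

well_formed_path <- function(path) {
  is.character(path) & nzchar(path) & startsWith(path, "\\") &
    endsWith(path, "\\")
}

## ---- fact construction ------------------------------------------------------

#' Build one observation-fact row
#'
#' @param patient_id,visit_id,concept_code,provider_id dimension foreign keys.
#' @param obs_date ISO-8601 observation date.
#' @param value_type one of `"none"`, `"numeric"`, `"text"`.
#' @param numeric_value required iff `value_type == "numeric"`.
#' @param text_value payload for text facts.
#' @param units unit string, `"%"` for percent-valued biomarkers.
#' @param instance_num positive integer discriminating repeated observations
#'   that share the other four key fields.
#' @return a one-row data frame in the fact-table layout.
#' @export
observation_fact <- function(patient_id, visit_id, concept_code, provider_id,
                             obs_date, value_type = "none",
                             numeric_value = NA_real_,
                             text_value = NA_character_,
                             units = "", instance_num = 1L) {
  if (!value_type %in% c("none", "numeric", "text"))
    dw_stop("dw_value_error", sprintf("invalid value_type '%s'", value_type))
  if ((value_type == "numeric") != !is.na(numeric_value))
    dw_stop("dw_value_error",
            "numeric_value must be present iff value_type is 'numeric'")
  data.frame(patient_id = patient_id, visit_id = visit_id,
             concept_code = concept_code, provider_id = provider_id,
             obs_date = obs_date, value_type = value_type,
             numeric_value = numeric_value, text_value = text_value,
             units = units, instance_num = as.integer(instance_num),
             stringsAsFactors = FALSE)
}

fact_key <- function(facts) {
  paste(facts$patient_id, facts$visit_id, facts$concept_code,
        facts$obs_date, facts$instance_num, sep = "\r")
}

## ---- insertion --------------------------------------------------------------

auto_register_stubs <- function(warehouse, facts) {
  miss_p <- setdiff(facts$patient_id, warehouse$patients$patient_id)
  if (length(miss_p))
    warehouse$patients <- rbind(warehouse$patients, data.frame(
      patient_id = miss_p, sex = "U", birth_date = NA_character_,
      vital_status = "unknown", death_date = NA_character_,
      stringsAsFactors = FALSE))
  miss_v <- !facts$visit_id %in% warehouse$visits$visit_id
  if (any(miss_v)) {
    nv <- unique(facts[miss_v, c("visit_id", "patient_id", "obs_date")])
    nv <- nv[!duplicated(nv$visit_id), ]
    warehouse$visits <- rbind(warehouse$visits, data.frame(
      visit_id = nv$visit_id, patient_id = nv$patient_id,
      start_date = nv$obs_date, end_date = nv$obs_date,
      location_code = "UNK", stringsAsFactors = FALSE))
  }
  miss_pr <- setdiff(facts$provider_id, warehouse$providers$provider_id)
  if (length(miss_pr))
    warehouse$providers <- rbind(warehouse$providers, data.frame(
      provider_id = miss_pr, name = miss_pr, department = "UNK",
      stringsAsFactors = FALSE))
  miss_c <- setdiff(facts$concept_code, warehouse$concepts$concept_code)
  if (length(miss_c)) {
    root <- "\\Unclassified\\"
    if (!root %in% warehouse$concepts$concept_path)
      warehouse$concepts <- rbind(warehouse$concepts, data.frame(
        concept_code = "DIM:UNCLASSIFIED", concept_path = root,
        name = "Unclassified", level = 1L, source = "OTHER",
        stringsAsFactors = FALSE))
    warehouse$concepts <- rbind(warehouse$concepts, data.frame(
      concept_code = miss_c, concept_path = paste0(root, miss_c, "\\"),
      name = miss_c, level = 2L, source = "OTHER", stringsAsFactors = FALSE))
  }
  warehouse
}

#' Insert or replace observation facts
#'
#' Facts whose unique key (patient, visit, concept, date, instance) already
#' exists replace the stored row (last-wins); duplicate keys within `facts`
#' keep the last occurrence.  With `auto_register = FALSE` (the default) every
#' foreign key must already resolve in its dimension table, otherwise an
#' integrity error naming the offending key is raised.
#'
#' @param warehouse a [new_warehouse()] object.
#' @param facts one or more fact rows ([observation_fact()] layout).
#' @param auto_register create stub dimension rows for unresolved keys
#'   (unknown concepts are registered under `\Unclassified\`).
#' @return the updated warehouse.
#' @export
upsert_fact <- function(warehouse, facts, auto_register = FALSE) {
  stopifnot(inherits(warehouse, "warehouse"))
  if (nrow(facts) == 0) return(warehouse)
  bad_type <- !facts$value_type %in% c("none", "numeric", "text")
  if (any(bad_type))
    dw_stop("dw_value_error", "invalid value_type in facts")
  mism <- (facts$value_type == "numeric") != !is.na(facts$numeric_value)
  if (any(mism))
    dw_stop("dw_value_error",
            "numeric_value must be present iff value_type is 'numeric'")
  if (auto_register) warehouse <- auto_register_stubs(warehouse, facts)
  check_fk <- function(keys, dim_keys, what) {
    miss <- setdiff(keys, dim_keys)
    if (length(miss))
      dw_stop("dw_integrity_error",
              sprintf("unresolved %s key(s): %s", what,
                      paste(miss, collapse = ", ")),
              table = what, keys = miss)
  }
  check_fk(facts$patient_id, warehouse$patients$patient_id, "patient")
  check_fk(facts$visit_id, warehouse$visits$visit_id, "visit")
  check_fk(facts$concept_code, warehouse$concepts$concept_code, "concept")
  check_fk(facts$provider_id, warehouse$providers$provider_id, "provider")

  facts <- facts[!duplicated(fact_key(facts), fromLast = TRUE), , drop = FALSE]
  existing <- warehouse$facts
  keep <- !fact_key(existing) %in% fact_key(facts)
  warehouse$facts <- rbind(existing[keep, , drop = FALSE], facts)
  rownames(warehouse$facts) <- NULL
  warehouse
}

## ---- integrity --------------------------------------------------------------

#' Check every table invariant of the warehouse
#'
#' Violations are returned as data, one row per broken rule, naming the table,
#' the offending key and the rule; an intact warehouse yields a zero-row frame.
#'
#' @param warehouse a warehouse.
#' @return data frame with columns `table`, `key`, `rule`.
#' @export
integrity_check <- function(warehouse) {
  v <- list()
  add <- function(table, key, rule) {
    if (length(key))
      v[[length(v) + 1]] <<- data.frame(table = table, key = as.character(key),
                                        rule = rule, stringsAsFactors = FALSE)
  }
  p <- warehouse$patients
  add("patients", p$patient_id[duplicated(p$patient_id)], "patient_id unique")
  dead <- !is.na(p$vital_status) & p$vital_status == "deceased"
  add("patients", p$patient_id[dead & is.na(p$death_date)],
      "death_date required when deceased")
  add("patients", p$patient_id[!dead & !is.na(p$death_date)],
      "death_date only when deceased")
  both <- !is.na(p$birth_date) & !is.na(p$death_date)
  if (any(both))
    add("patients", p$patient_id[both][!date_le(p$birth_date[both],
                                                p$death_date[both])],
        "birth_date <= death_date")

  vis <- warehouse$visits
  add("visits", vis$visit_id[duplicated(vis$visit_id)], "visit_id unique")
  ok_dates <- !is.na(vis$start_date) & !is.na(vis$end_date)
  if (any(ok_dates))
    add("visits", vis$visit_id[ok_dates][!date_le(vis$start_date[ok_dates],
                                                  vis$end_date[ok_dates])],
        "start_date <= end_date")
  add("visits", vis$visit_id[!vis$patient_id %in% p$patient_id],
      "patient_id resolves")

  pr <- warehouse$providers
  add("providers", pr$provider_id[duplicated(pr$provider_id)],
      "provider_id unique")

  co <- warehouse$concepts
  add("concepts", co$concept_path[duplicated(co$concept_path)],
      "concept_path unique")
  add("concepts", co$concept_path[!well_formed_path(co$concept_path)],
      "path delimited")
  lv <- path_level(co$concept_path)
  add("concepts", co$concept_path[lv != co$level],
      "level = number of path segments")
  par <- parent_path(co$concept_path)
  need_parent <- co$level > 1L
  add("concepts", co$concept_path[need_parent &
                                    !par %in% co$concept_path],
      "parent path present")

  f <- warehouse$facts
  add("facts", fact_key(f)[duplicated(fact_key(f))], "fact key unique")
  add("facts", f$patient_id[!f$patient_id %in% p$patient_id],
      "patient_id resolves")
  add("facts", f$visit_id[!f$visit_id %in% vis$visit_id], "visit_id resolves")
  add("facts", f$concept_code[!f$concept_code %in% co$concept_code],
      "concept_code resolves")
  add("facts", f$provider_id[!f$provider_id %in% pr$provider_id],
      "provider_id resolves")
  add("facts",
      fact_key(f)[(f$value_type == "numeric") != !is.na(f$numeric_value)],
      "numeric_value iff value_type numeric")
  if (length(v)) do.call(rbind, v)
  else data.frame(table = character(0), key = character(0),
                  rule = character(0), stringsAsFactors = FALSE)
}

## ---- summary counts ---------------------------------------------------------

#' Warehouse summary counts
#'
#' @param warehouse a warehouse.
#' @param biobank_path concept-path prefix of the biobank branch; a patient is
#'   "biobanked" when at least one of their facts falls under it.
#' @return named list: `n_patients`, `n_visits`, `n_facts`, `n_concepts`,
#'   `n_biobanked_patients`.
#' @export
warehouse_counts <- function(warehouse, biobank_path = "\\Biobank\\") {
  bb_codes <- warehouse$concepts$concept_code[
    path_has_prefix(warehouse$concepts$concept_path, biobank_path)]
  bb_pat <- unique(warehouse$facts$patient_id[
    warehouse$facts$concept_code %in% bb_codes])
  list(n_patients = nrow(warehouse$patients),
       n_visits = nrow(warehouse$visits),
       n_facts = nrow(warehouse$facts),
       n_concepts = nrow(warehouse$concepts),
       n_biobanked_patients = length(bb_pat))
}

## ---- import / export --------------------------------------------------------

WAREHOUSE_FILES <- c(patients = "patients.tsv", visits = "visits.tsv",
                     providers = "providers.tsv", concepts = "concepts.tsv",
                     facts = "observation_facts.tsv")

#' Export a warehouse as five delimited text tables
#'
#' @param warehouse a warehouse.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
export_warehouse <- function(warehouse, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tb in names(WAREHOUSE_FILES))
    dw_write_table(warehouse[[tb]], file.path(dir, WAREHOUSE_FILES[[tb]]))
  invisible(dir)
}

#' Import a warehouse from its exported table files
#'
#' @param dir directory written by [export_warehouse()].
#' @return a warehouse.
#' @export
import_warehouse <- function(dir) {
  wh <- new_warehouse()
  wh$patients  <- dw_read_table(file.path(dir, WAREHOUSE_FILES[["patients"]]))
  wh$visits    <- dw_read_table(file.path(dir, WAREHOUSE_FILES[["visits"]]))
  wh$providers <- dw_read_table(file.path(dir, WAREHOUSE_FILES[["providers"]]))
  wh$concepts  <- dw_read_table(file.path(dir, WAREHOUSE_FILES[["concepts"]]),
                                integer_cols = "level")
  wh$facts     <- dw_read_table(file.path(dir, WAREHOUSE_FILES[["facts"]]),
                                numeric_cols = "numeric_value",
                                integer_cols = "instance_num")
  blank_na <- function(x) ifelse(x == "", NA_character_, x)
  wh$patients$death_date <- blank_na(wh$patients$death_date)
  wh$patients$birth_date <- blank_na(wh$patients$birth_date)
  wh$facts$text_value <- blank_na(wh$facts$text_value)
  wh
}
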