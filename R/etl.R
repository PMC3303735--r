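## Incremental pathology-unit -> biobank synchronization (anonymization
## happens in flight: every admitted specimen gets a fresh barcode and a
## lookup link) and the periodic merge that populates the warehouse from
## biobank + HIS + report-extraction outputs.  Scheduling (the real system
## syncs every few minutes and merges weekly) is modelled as explicit calls
## carrying timestamps, which keeps both operations replayable and testable.

MATERIAL_TYPES <- c("tissue", "blood", "plasma", "serum", "DNA", "RNA",
                    "other")
BIOBANK_PROJECTS <- c("BREAST-01", "TRIAL-A", "ARCHIVE")
SAMPLE_TYPES <- c("primary", "metastatic", "normal")

BIOBANK_COLS <- c(payload = "character", material_type = "character",
                  fridge_position = "character", consent_research = "logical",
                  project = "character", sample_type = "character",
                  creation_date = "character", description = "character")

#' Create an empty biobank sample store
#'
#' One row per anonymized specimen: barcode payload, material type, fridge
#' position, research-consent flag and the meta-attributes (project, sample
#' type, creation date, description).
#'
#' @return data frame in the biobank layout.
#' @export
new_biobank <- function() empty_df(BIOBANK_COLS)

#' @rdname new_biobank
#' @param biobank biobank store.
#' @param dir store directory.
#' @export
save_biobank <- function(biobank, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dw_write_table(biobank, file.path(dir, "biobank_samples.tsv"))
  invisible(dir)
}

#' @rdname new_biobank
#' @export
load_biobank <- function(dir) {
  f <- file.path(dir, "biobank_samples.tsv")
  if (!file.exists(f)) return(new_biobank())
  dw_read_table(f, logical_cols = "consent_research")
}

#' Create a fresh synchronization state
#'
#' @param last_sync_timestamp ISO datetime; only source rows strictly newer
#'   are processed.
#' @return a `sync_state`.
#' @export
new_sync_state <- function(last_sync_timestamp = "1970-01-01T00:00:00") {
  structure(list(last_sync_timestamp = last_sync_timestamp,
                 processed_ids = character(0)), class = "sync_state")
}

#' Synchronize new pathology-unit specimens into the biobank
#'
#' Processes only source rows newer than the state's watermark: consented,
#' well-formed specimens receive a fresh PHI-free barcode ([new_barcode()],
#' deny-listed against every identifier field in the source table) and a
#' lookup link; non-consented specimens are skipped; malformed rows are
#' quarantined with a log entry and the sync continues.  Re-running with an
#' unchanged source is a no-op.
#'
#' @param pu_specimens pathology-unit specimen table with columns
#'   `pu_specimen_id`, `pu_patient_id`, `material_type`, `fridge_position`,
#'   `consent_research`, `project`, `sample_type`, `creation_date`,
#'   `description`, `updated_at`, plus any identifier columns (`given_name`,
#'   `family_name`).
#' @param biobank biobank store ([new_biobank()]).
#' @param lookup a [new_lookup()].
#' @param state a [new_sync_state()].
#' @return list with updated `biobank`, `lookup`, `state` and a `log` frame
#'   (`pu_specimen_id`, `action`, `reason`).
#' @export
sync_pu_to_biobank <- function(pu_specimens, biobank, lookup, state) {
  stopifnot(inherits(state, "sync_state"), inherits(lookup, "bb_lookup"))
  idcols <- intersect(c("given_name", "family_name"), names(pu_specimens))
  deny <- unique(unlist(pu_specimens[idcols], use.names = FALSE))
  fresh <- pu_specimens$updated_at > state$last_sync_timestamp &
    !pu_specimens$pu_specimen_id %in% state$processed_ids
  todo <- pu_specimens[fresh, , drop = FALSE]
  todo <- todo[order(todo$pu_specimen_id), , drop = FALSE]
  log <- list()
  note <- function(id, action, reason)
    log[[length(log) + 1]] <<- data.frame(pu_specimen_id = id,
                                          action = action, reason = reason,
                                          stringsAsFactors = FALSE)
  for (i in seq_len(nrow(todo))) {
    row <- todo[i, ]
    if (is.na(row$material_type) || !row$material_type %in% MATERIAL_TYPES ||
        is.na(row$creation_date) || !is_iso_date(row$creation_date)) {
      note(row$pu_specimen_id, "quarantined", "malformed record")
      next
    }
    if (!isTRUE(row$consent_research)) {
      note(row$pu_specimen_id, "skipped", "no research consent")
      next
    }
    payload <- new_barcode(lookup, deny = deny)
    lookup <- link_payload(lookup, row$pu_patient_id, payload)
    biobank <- rbind(biobank, data.frame(
      payload = payload, material_type = row$material_type,
      fridge_position = row$fridge_position,
      consent_research = TRUE, project = row$project,
      sample_type = row$sample_type, creation_date = row$creation_date,
      description = row$description, stringsAsFactors = FALSE))
    note(row$pu_specimen_id, "synced", "")
  }
  if (nrow(todo))
    state$last_sync_timestamp <- max(state$last_sync_timestamp,
                                     max(todo$updated_at))
  state$processed_ids <- union(state$processed_ids, todo$pu_specimen_id)
  list(biobank = biobank, lookup = lookup, state = state,
       log = if (length(log)) do.call(rbind, log)
             else data.frame(pu_specimen_id = character(0),
                             action = character(0), reason = character(0),
                             stringsAsFactors = FALSE))
}

## ---- concept dimension ------------------------------------------------------

branch_concepts <- function(root_name, root_code, source, children) {
  root_path <- paste0("\\", root_name, "\\")
  rows <- data.frame(concept_code = root_code, concept_path = root_path,
                     name = root_name, level = 1L, source = source,
                     stringsAsFactors = FALSE)
  for (ch in children) {
    sub_path <- paste0(root_path, ch$name, "\\")
    rows <- rbind(rows, data.frame(concept_code = ch$code,
                                   concept_path = sub_path, name = ch$name,
                                   level = 2L, source = source,
                                   stringsAsFactors = FALSE))
    for (leaf in ch$leaves %||% list())
      rows <- rbind(rows, data.frame(
        concept_code = leaf$code,
        concept_path = paste0(sub_path, leaf$name, "\\"),
        name = leaf$name, level = 3L, source = source,
        stringsAsFactors = FALSE))
  }
  rows
}

leafset <- function(codes, names) Map(function(c, n) list(code = c, name = n),
                                      codes, names)

#' Build the full queryable concept dimension
#'
#' Combines the SNOMED-style morphology subtree (via [build_concepts()])
#' with the internal hierarchy covering demographics, TNM components (one
#' concept per T/N/M value), biomarkers, and the biobank branch (material
#' types plus the project and sample-type meta-attributes promoted to
#' queryable concepts).
#'
#' @param tree an [ontology_source()]; defaults to the packaged morphology
#'   tree.
#' @param projects,sample_types biobank meta-attribute vocabularies.
#' @return concept data frame for the warehouse concept dimension.
#' @export
build_concept_dimension <- function(tree = default_term_tree(),
                                    projects = BIOBANK_PROJECTS,
                                    sample_types = SAMPLE_TYPES) {
  snomed <- build_concepts(tree$root, "\\SNOMED\\", "SNOMED")
  demo <- branch_concepts("Demographics", "DIM:DEMOGRAPHICS", "DEMOGRAPHIC",
    list(list(code = "DEM:SEX", name = "Sex",
              leaves = leafset(c("DEM:SEX:F", "DEM:SEX:M", "DEM:SEX:U"),
                               c("Female", "Male", "Unknown sex"))),
         list(code = "DEM:VITAL", name = "Vital status",
              leaves = leafset(c("DEM:VITAL:ALIVE", "DEM:VITAL:DECEASED",
                                 "DEM:VITAL:UNKNOWN"),
                               c("Alive", "Deceased",
                                 "Unknown vital status")))))
  tnm <- branch_concepts("TNM", "DIM:TNM", "TNM",
    list(list(code = "TNM:T", name = "T",
              leaves = leafset(paste0("TNM:T", TNM_T_VALUES),
                               paste0("T", TNM_T_VALUES))),
         list(code = "TNM:N", name = "N",
              leaves = leafset(paste0("TNM:N", TNM_N_VALUES),
                               paste0("N", TNM_N_VALUES))),
         list(code = "TNM:M", name = "M",
              leaves = leafset(paste0("TNM:M", TNM_M_VALUES),
                               paste0("M", TNM_M_VALUES)))))
  bmk <- branch_concepts("Biomarkers", "DIM:BIOMARKERS", "BIOMARKER",
    list(list(code = "BMK:ER", name = "Estrogen receptors"),
                     list(code = "BMK:PR", name = "Progesterone receptors"),
                     list(code = "BMK:KI67", name = "Ki-67"),
                     list(code = "BMK:HER2", name = "HER-2 score"),
                     list(code = "BMK:GRADE", name = "Grade")))
  material_names <- c(tissue = "Tissue", blood = "Blood", plasma = "Plasma",
                      serum = "Serum", DNA = "DNA", RNA = "RNA",
                      other = "Other material")
  bb <- branch_concepts("Biobank", "DIM:BIOBANK", "BIOBANK",
    c(unname(Map(function(mt, nm) list(code = paste0("BB:", toupper(mt)),
                                       name = nm),
                 names(material_names), material_names)),
      list(list(code = "BB:PROJ", name = "Project",
                leaves = leafset(paste0("BB:PROJ:", projects), projects)),
           list(code = "BB:STYPE", name = "Sample type",
                leaves = leafset(paste0("BB:STYPE:", toupper(sample_types)),
                                 tools::toTitleCase(sample_types))))))
  rbind(snomed, demo, tnm, bmk, bb)
}

material_concept <- function(material_type) paste0("BB:", toupper(material_type))

## ---- warehouse load ---------------------------------------------------------

default_providers <- function() {
  data.frame(provider_id = c("PROV-PATH", "PROV-ONC"),
             name = c("Pathology unit", "Oncology unit"),
             department = c("Pathology", "Oncology"),
             stringsAsFactors = FALSE)
}

## first visit of each patient (earliest start date, ties by visit id)
first_visits <- function(visits) {
  o <- order(visits$patient_id, visits$start_date, visits$visit_id)
  v <- visits[o, , drop = FALSE]
  v[!duplicated(v$patient_id), , drop = FALSE]
}

visit_for_date <- function(visits, patient_id, date, fallback) {
  cand <- visits[visits$patient_id == patient_id, , drop = FALSE]
  if (!nrow(cand)) return(NA_character_)
  hit <- cand[date_le(cand$start_date, date) & date_le(date, cand$end_date), ,
              drop = FALSE]
  if (nrow(hit)) {
    hit <- hit[order(hit$start_date, hit$visit_id), , drop = FALSE]
    return(hit$visit_id[1])
  }
  if (isTRUE(fallback)) {
    cand <- cand[order(cand$start_date, cand$visit_id), , drop = FALSE]
    return(cand$visit_id[1])
  }
  NA_character_
}

#' Merge HIS, report extractions and biobank samples into the warehouse
#'
#' Mapping rules: each HIS visit becomes a visit-dimension row; sex and vital
#' status become facts under the demographic branch; each extraction result
#' yields one fact per SNOMED pair, one fact per TNM component, and numeric
#' facts (units `"%"` where applicable) for grade, ER, PR, Ki-67 and HER-2
#' under the biomarker branch (qualitative receptor status becomes a text
#' fact); each consented biobank sample yields a fact at
#' `\Biobank\<material>\` (with the free-text description as annotation)
#' plus project and sample-type meta-attribute facts.  SNOMED codes missing
#' from the concept dimension are logged and skipped; extractions whose
#' report cannot be tied to an HIS patient are orphans.  Patient identifiers
#' never enter the warehouse: patients are keyed by segregated-lookup
#' pseudonyms.  The whole load is key-idempotent.
#'
#' @param warehouse target warehouse.
#' @param concepts concept dimension ([build_concept_dimension()]).
#' @param his list with `patients` (pu_patient_id, sex, birth_date,
#'   vital_status, death_date) and `visits` (visit_id, pu_patient_id,
#'   start_date, end_date, location_code).
#' @param extractions list of [extraction_result()]s.
#' @param biobank biobank store.
#' @param lookup a [new_lookup()]; pseudonyms are minted here as needed.
#' @param report_map data frame `report_id`, `pu_patient_id` linking
#'   anonymized report ids back to source patients.
#' @return list with `warehouse`, `lookup` and `report` (`facts_written`,
#'   `skipped`, `orphans`, `quarantined`, `messages`).
#' @export
load_warehouse <- function(warehouse, concepts, his, extractions, biobank,
                           lookup, report_map) {
  stopifnot(inherits(warehouse, "warehouse"))
  messages <- character(0)
  skipped <- 0L
  orphans <- character(0)

  ## dimensions ---------------------------------------------------------------
  warehouse$concepts <- concepts
  hp <- his$patients[order(his$patients$pu_patient_id), , drop = FALSE]
  wid <- character(nrow(hp))
  for (i in seq_len(nrow(hp))) {
    ps <- pseudonym_for(lookup, hp$pu_patient_id[i])
    lookup <- ps$lookup
    wid[i] <- ps$warehouse_id
  }
  warehouse$patients <- data.frame(
    patient_id = wid, sex = hp$sex, birth_date = hp$birth_date,
    vital_status = hp$vital_status, death_date = hp$death_date,
    stringsAsFactors = FALSE)
  pid_of <- setNames(wid, hp$pu_patient_id)
  hv <- his$visits[order(his$visits$visit_id), , drop = FALSE]
  warehouse$visits <- data.frame(
    visit_id = hv$visit_id, patient_id = unname(pid_of[hv$pu_patient_id]),
    start_date = hv$start_date, end_date = hv$end_date,
    location_code = hv$location_code, stringsAsFactors = FALSE)
  warehouse$providers <- default_providers()

  wv <- warehouse$visits
  fv <- first_visits(wv)
  first_visit_of <- setNames(fv$visit_id, fv$patient_id)
  first_date_of <- setNames(fv$start_date, fv$patient_id)

  facts <- list()
  emit <- function(patient_id, visit_id, concept_code, provider_id, obs_date,
                   value_type = "none", numeric_value = NA_real_,
                   text_value = NA_character_, units = "") {
    facts[[length(facts) + 1]] <<- data.frame(
      patient_id = patient_id, visit_id = visit_id,
      concept_code = concept_code, provider_id = provider_id,
      obs_date = obs_date, value_type = value_type,
      numeric_value = numeric_value, text_value = text_value, units = units,
      instance_num = 1L, stringsAsFactors = FALSE)
  }

  ## demographics -------------------------------------------------------------
  for (i in seq_len(nrow(warehouse$patients))) {
    p <- warehouse$patients[i, ]
    visit <- first_visit_of[p$patient_id]
    if (is.na(visit)) {
      messages <- c(messages,
                    sprintf("patient %s has no visits; demographics skipped",
                            p$patient_id))
      next
    }
    d <- first_date_of[p$patient_id]
    emit(p$patient_id, visit, paste0("DEM:SEX:", p$sex), "PROV-ONC", d)
    emit(p$patient_id, visit,
         paste0("DEM:VITAL:", toupper(p$vital_status)), "PROV-ONC", d)
  }

  ## report extractions -------------------------------------------------------
  ord <- order(vapply(extractions, `[[`, character(1), "name"))
  for (res in extractions[ord]) {
    j <- match(res$name, report_map$report_id)
    pu <- if (is.na(j)) NA_character_ else report_map$pu_patient_id[j]
    patient <- if (is.na(pu)) NA_character_ else unname(pid_of[pu])
    if (is.na(patient)) {
      orphans <- c(orphans, res$name)
      messages <- c(messages,
                    sprintf("report %s: no HIS patient; extraction skipped",
                            res$name))
      next
    }
    visit <- visit_for_date(wv, patient, res$date, fallback = TRUE)
    d <- res$date
    for (k in seq_len(nrow(res$snomed))) {
      code <- res$snomed$code[k]
      if (!code %in% concepts$concept_code) {
        skipped <- skipped + 1L
        messages <- c(messages,
                      sprintf("report %s: code %s not in concept dimension; skipped",
                              res$name, code))
        next
      }
      emit(patient, visit, code, "PROV-PATH", d)
    }
    if (!is.null(res$state)) {
      emit(patient, visit, paste0("TNM:T", res$state$t), "PROV-PATH", d)
      emit(patient, visit, paste0("TNM:N", res$state$n), "PROV-PATH", d)
      emit(patient, visit, paste0("TNM:M", res$state$m), "PROV-PATH", d)
    }
    if (!is.na(res$grade))
      emit(patient, visit, "BMK:GRADE", "PROV-PATH", d, "numeric",
           as.numeric(res$grade))
    if (!is.na(res$estrogens_receptors))
      emit(patient, visit, "BMK:ER", "PROV-PATH", d, "numeric",
           res$estrogens_receptors, units = "%")
    else if (!is.na(res$estrogens_receptors_status))
      emit(patient, visit, "BMK:ER", "PROV-PATH", d, "text",
           text_value = res$estrogens_receptors_status)
    if (!is.na(res$progesterone_receptors))
      emit(patient, visit, "BMK:PR", "PROV-PATH", d, "numeric",
           res$progesterone_receptors, units = "%")
    else if (!is.na(res$progesterone_receptors_status))
      emit(patient, visit, "BMK:PR", "PROV-PATH", d, "text",
           text_value = res$progesterone_receptors_status)
    if (!is.na(res$ki67))
      emit(patient, visit, "BMK:KI67", "PROV-PATH", d, "numeric", res$ki67,
           units = "%")
    if (!is.na(res$c_erb_b2))
      emit(patient, visit, "BMK:HER2", "PROV-PATH", d, "numeric",
           as.numeric(res$c_erb_b2))
  }

  ## biobank samples ----------------------------------------------------------
  bb <- biobank[order(biobank$payload), , drop = FALSE]
  for (i in seq_len(nrow(bb))) {
    s <- bb[i, ]
    if (!isTRUE(s$consent_research)) next
    pu <- resolve_payload(lookup, s$payload, authorized = TRUE)
    patient <- unname(pid_of[pu])
    if (is.na(patient)) {
      messages <- c(messages,
                    sprintf("sample %s: donor not in HIS; skipped", s$payload))
      next
    }
    visit <- visit_for_date(wv, patient, s$creation_date, fallback = TRUE)
    emit(patient, visit, material_concept(s$material_type), "PROV-PATH",
         s$creation_date, "text", text_value = s$description)
    emit(patient, visit, paste0("BB:PROJ:", s$project), "PROV-PATH",
         s$creation_date)
    emit(patient, visit, paste0("BB:STYPE:", toupper(s$sample_type)),
         "PROV-PATH", s$creation_date)
  }

  fact_df <- if (length(facts)) do.call(rbind, facts)
    else empty_df(FACT_COLS)
  if (nrow(fact_df)) {
    key <- paste(fact_df$patient_id, fact_df$visit_id, fact_df$concept_code,
                 fact_df$obs_date, sep = "\r")
    fact_df$instance_num <- as.integer(stats::ave(seq_len(nrow(fact_df)), key,
                                                  FUN = seq_along))
  }
  warehouse <- upsert_fact(warehouse, fact_df)
  list(warehouse = warehouse, lookup = lookup,
       report = list(facts_written = nrow(fact_df), skipped = skipped,
                     orphans = orphans, quarantined = 0L,
                     messages = messages))
}

#' Summarize a load result
#'
#' @param result the `report` component returned by [load_warehouse()],
#'   optionally with `quarantined` patched in from a sync log.
#' @return data frame with one row: `facts_written`, `skipped`, `orphans`,
#'   `quarantined`.
#' @export
load_report <- function(result) {
  stopifnot(is.numeric(result$facts_written), result$facts_written >= 0,
            result$skipped >= 0)
  data.frame(facts_written = as.integer(result$facts_written),
             skipped = as.integer(result$skipped),
             orphans = length(result$orphans),
             quarantined = as.integer(result$quarantined %||% 0L),
             stringsAsFactors = FALSE)
}
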