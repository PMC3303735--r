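## Boolean patient-set queries in the panel model: items within a panel are
## OR-ed (a patient qualifies through any item's concept subtree), panels are
## AND-ed, and a panel may be inverted against the whole patient dimension.
## Value and date constraints bind to the same fact that matched the concept.

#' Build a query panel
#'
#' @param items character vector of concept paths; each is expanded to its
#'   descendants ([concept_descendants()]).
#' @param value_op optional numeric constraint operator: `">="`, `"<="`,
#'   `"="` or `"between"`.
#' @param value,value2 constraint bounds (`value2` only for `between`;
#'   bounds must be ordered).
#' @param date_from,date_to optional ISO-8601 observation-date range.
#' @param invert complement the panel result against all patients.
#' @return a `query_panel`.
#' @export
query_panel <- function(items, value_op = NULL, value = NULL, value2 = NULL,
                        date_from = NULL, date_to = NULL, invert = FALSE) {
  if (!length(items))
    dw_stop("dw_value_error", "panel items must be non-empty")
  if (!all(well_formed_path(items)))
    dw_stop("dw_value_error", "malformed concept path in panel items")
  if (!is.null(value_op)) {
    if (!value_op %in% c(">=", "<=", "=", "between"))
      dw_stop("dw_value_error", sprintf("invalid operator '%s'", value_op))
    if (is.null(value))
      dw_stop("dw_value_error", "value constraint requires a bound")
    if (value_op == "between") {
      if (is.null(value2) || value2 < value)
        dw_stop("dw_value_error", "'between' requires ordered bounds")
    }
  }
  structure(list(items = items, value_op = value_op, value = value,
                 value2 = value2, date_from = date_from, date_to = date_to,
                 invert = isTRUE(invert)), class = "query_panel")
}

#' Build a query definition (ordered panels, AND-ed)
#'
#' @param ... `query_panel` objects, or a single list of them.
#' @return a `query_definition`.
#' @export
query_definition <- function(...) {
  panels <- list(...)
  if (length(panels) == 1 && !inherits(panels[[1]], "query_panel"))
    panels <- panels[[1]]
  if (!length(panels))
    dw_stop("dw_value_error", "a query needs at least one panel")
  stopifnot(all(vapply(panels, inherits, logical(1), "query_panel")))
  structure(list(panels = panels), class = "query_definition")
}

#' Evaluate one panel against the warehouse
#'
#' A patient qualifies when some fact of theirs sits at a concept in the
#' descendant set of any item and satisfies the value and date constraints;
#' `invert` complements the result against the patient dimension.  Value
#' constraints apply to numeric facts; a constraint on a panel whose
#' expansion contains no numeric-valued (biomarker) concept is a type error.
#'
#' @param panel a [query_panel()].
#' @param warehouse a warehouse.
#' @param concepts concept dimension (defaults to the warehouse's own).
#' @return character vector of patient ids.
#' @export
eval_panel <- function(panel, warehouse, concepts = warehouse$concepts) {
  stopifnot(inherits(panel, "query_panel"))
  codes <- unique(unlist(lapply(panel$items, function(p)
    concept_descendants(concepts, p)$concept_code)))
  f <- warehouse$facts[warehouse$facts$concept_code %in% codes, ,
                       drop = FALSE]
  if (!is.null(panel$date_from))
    f <- f[date_le(panel$date_from, f$obs_date), , drop = FALSE]
  if (!is.null(panel$date_to))
    f <- f[date_le(f$obs_date, panel$date_to), , drop = FALSE]
  if (!is.null(panel$value_op)) {
    src <- concepts$source[match(codes, concepts$concept_code)]
    if (!any(src == "BIOMARKER", na.rm = TRUE))
      dw_stop("dw_type_error",
              "value constraint applied to a non-numeric concept")
    num <- f[f$value_type == "numeric", , drop = FALSE]
    x <- num$numeric_value
    keep <- switch(panel$value_op,
                   ">=" = x >= panel$value,
                   "<=" = x <= panel$value,
                   "="  = x == panel$value,
                   "between" = x >= panel$value & x <= panel$value2)
    f <- num[keep, , drop = FALSE]
  }
  ids <- unique(f$patient_id)
  if (panel$invert) setdiff(warehouse$patients$patient_id, ids) else ids
}

#' Run a query definition: AND across panels
#'
#' @param definition a [query_definition()].
#' @param warehouse a warehouse.
#' @param concepts concept dimension.
#' @param created_at provenance timestamp (defaults to now).
#' @return a `patient_set` with `patient_ids` and `provenance`.
#' @export
run_query <- function(definition, warehouse, concepts = warehouse$concepts,
                      created_at = NULL) {
  stopifnot(inherits(definition, "query_definition"))
  sets <- lapply(definition$panels, eval_panel, warehouse = warehouse,
                 concepts = concepts)
  ids <- Reduce(intersect, sets)
  structure(list(patient_ids = sort(ids),
                 provenance = list(
                   definition = definition,
                   created_at = created_at %||%
                     format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
            class = "patient_set")
}

#' @export
print.patient_set <- function(x, ...) {
  cat(sprintf("<patient_set> %d patients (created %s, %d panel(s))\n",
              length(x$patient_ids), x$provenance$created_at,
              length(x$provenance$definition$panels)))
  invisible(x)
}

## ---- patient-set and definition files --------------------------------------

serialize_panel <- function(p) {
  enc <- function(x) if (is.null(x)) "" else as.character(x)
  paste0("items=", paste(p$items, collapse = "|"),
         ";op=", enc(p$value_op), ";value=", enc(p$value),
         ";value2=", enc(p$value2), ";from=", enc(p$date_from),
         ";to=", enc(p$date_to), ";invert=", as.integer(p$invert))
}

deserialize_panel <- function(line) {
  kv <- regmatches(line,
                   gregexpr("(items|op|value|value2|from|to|invert)=[^;]*",
                            line))[[1]]
  if (!length(kv)) dw_stop("dw_parse_error",
                           sprintf("malformed panel line: %s", line))
  get <- function(key) {
    hit <- kv[startsWith(kv, paste0(key, "="))]
    if (!length(hit)) return(NULL)
    val <- sub("^[a-z0-9]+=", "", hit[1])
    if (nzchar(val)) val else NULL
  }
  items <- strsplit(get("items") %||%
                      dw_stop("dw_parse_error", "panel without items"),
                    "|", fixed = TRUE)[[1]]
  num <- function(x) if (is.null(x)) NULL else as.numeric(x)
  query_panel(items, value_op = get("op"), value = num(get("value")),
              value2 = num(get("value2")), date_from = get("from"),
              date_to = get("to"),
              invert = identical(get("invert"), "1"))
}

#' Save / load a query definition as a structured text file
#'
#' One panel per non-comment line (`items=...;op=...;...`).
#'
#' @param definition a [query_definition()].
#' @param path file path.
#' @return `save_query_definition`: the path, invisibly;
#'   `load_query_definition`: a `query_definition`.
#' @export
save_query_definition <- function(definition, path) {
  writeLines(c("# oncodw query definition",
               vapply(definition$panels, serialize_panel, character(1))),
             path, useBytes = TRUE)
  invisible(path)
}

#' @rdname save_query_definition
#' @export
load_query_definition <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(lines))
    dw_stop("dw_parse_error", "no panels in query definition file")
  query_definition(lapply(lines, deserialize_panel))
}

#' Save / load a patient set as one-id-per-line text with provenance header
#'
#' @param patient_set a `patient_set`.
#' @param path file path.
#' @return `save_patient_set`: the path, invisibly; `load_patient_set`: a
#'   `patient_set`.
#' @export
save_patient_set <- function(patient_set, path) {
  stopifnot(inherits(patient_set, "patient_set"))
  hdr <- c("# oncodw patient set",
           paste0("# created_at: ", patient_set$provenance$created_at),
           vapply(patient_set$provenance$definition$panels,
                  function(p) paste0("# panel: ", serialize_panel(p)),
                  character(1)))
  writeLines(c(hdr, patient_set$patient_ids), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname save_patient_set
#' @export
load_patient_set <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (!length(lines) || lines[1] != "# oncodw patient set")
    dw_stop("dw_parse_error",
            sprintf("not a patient-set file: %s", path))
  created <- sub("^# created_at: ", "",
                 lines[startsWith(lines, "# created_at: ")][1])
  panel_lines <- sub("^# panel: ", "",
                     lines[startsWith(lines, "# panel: ")])
  ids <- lines[!startsWith(lines, "#") & nzchar(lines)]
  definition <- if (length(panel_lines))
    query_definition(lapply(panel_lines, deserialize_panel))
  else query_definition(query_panel("\\", invert = TRUE))
  structure(list(patient_ids = ids,
                 provenance = list(definition = definition,
                                   created_at = created)),
            class = "patient_set")
}
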