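## PHI-free sample identifiers and the segregated donor lookup table.
## A barcode payload is the textual content of a DataMatrix label:
## fixed prefix + 10 characters from the Crockford base-32 alphabet
## (no I, L, O, U, so mistranscription-prone glyphs never occur) + one
## mod-37 check character.  The payload never encodes anything about the
## donor; the only link back to the pathology-unit patient identifier lives
## in a lookup table kept in its own store, physically separate from the
## warehouse and biobank exports.

BARCODE_ALPHABET <- strsplit("0123456789ABCDEFGHJKMNPQRSTVWXYZ", "")[[1]]
BARCODE_CHECK_ALPHABET <- c(BARCODE_ALPHABET, "*", "~", "$", "=", "U")
BARCODE_PREFIX <- "FSM-BB-"
BARCODE_BODY_LEN <- 10L

barcode_check_char <- function(body) {
  idx <- match(strsplit(body, "")[[1]], BARCODE_ALPHABET) - 1L
  v <- 0L
  for (d in idx) v <- (v * 32L + d) %% 37L
  BARCODE_CHECK_ALPHABET[v + 1L]
}

#' Verify a barcode payload's format and check character
#'
#' @param payload payload string.
#' @return `TRUE` iff the payload has the expected prefix, body alphabet and
#'   a valid check character.
#' @export
verify_barcode <- function(payload) {
  if (!is.character(payload) || length(payload) != 1 || is.na(payload))
    return(FALSE)
  if (!startsWith(payload, BARCODE_PREFIX)) return(FALSE)
  rest <- substring(payload, nchar(BARCODE_PREFIX) + 1)
  if (nchar(rest) != BARCODE_BODY_LEN + 1L) return(FALSE)
  body <- substring(rest, 1, BARCODE_BODY_LEN)
  if (!all(strsplit(body, "")[[1]] %in% BARCODE_ALPHABET)) return(FALSE)
  substring(rest, BARCODE_BODY_LEN + 1L) == barcode_check_char(body)
}

#' Generate a fresh, unique, PHI-free barcode payload
#'
#' Draws payload bodies from R's random number stream (seed with `set.seed()`
#' for reproducible sequences) until one is unused in `lookup` and passes
#' [assert_no_phi()] against `deny` — so PHI-freedom is guaranteed by
#' construction, not by chance.
#'
#' @param lookup a [new_lookup()]; generated payloads never collide with its
#'   entries.
#' @param deny character vector of donor identifier strings the payload must
#'   not contain any length-4+ substring of.
#' @param max_tries attempts before a capacity error.
#' @return a payload string.
#' @export
new_barcode <- function(lookup = new_lookup(), deny = character(0),
                        max_tries = 10000L) {
  for (i in seq_len(max_tries)) {
    body <- paste(sample(BARCODE_ALPHABET, BARCODE_BODY_LEN, replace = TRUE),
                  collapse = "")
    payload <- paste0(BARCODE_PREFIX, body, barcode_check_char(body))
    if (payload %in% lookup$barcodes$payload) next
    if (!assert_no_phi(payload, deny)) next
    return(payload)
  }
  dw_stop("dw_capacity_error",
          sprintf("could not draw a fresh payload in %d tries", max_tries))
}

#' Assert that a payload carries no donor information
#'
#' Case-normalized scan: `TRUE` iff no substring of length >= 4 of any
#' patient identifier field occurs in the payload.
#'
#' @param payload payload string.
#' @param patient_fields character vector of identifier field values.
#' @return logical.
#' @export
assert_no_phi <- function(payload, patient_fields) {
  if (!length(patient_fields)) return(TRUE)
  hay <- toupper(payload)
  for (field in patient_fields) {
    f <- toupper(field)
    n <- nchar(f)
    if (is.na(f) || n < 4) next
    for (i in seq_len(n - 3L))
      if (grepl(substring(f, i, i + 3L), hay, fixed = TRUE)) return(FALSE)
  }
  TRUE
}

## ---- lookup table -----------------------------------------------------------

#' Create an empty segregated lookup table
#'
#' Holds two maps: barcode payload -> pathology-unit patient id, and
#' pathology-unit patient id -> warehouse pseudonym.  The warehouse and
#' biobank stores carry only payloads and pseudonyms; source patient ids
#' exist solely here.
#'
#' @return an object of class `bb_lookup`.
#' @export
new_lookup <- function() {
  structure(list(
    barcodes = data.frame(payload = character(0),
                          pu_patient_id = character(0),
                          stringsAsFactors = FALSE),
    pseudonyms = data.frame(pu_patient_id = character(0),
                            warehouse_id = character(0),
                            stringsAsFactors = FALSE)),
    class = "bb_lookup")
}

#' Link a payload to a pathology-unit patient id
#'
#' Re-linking an existing pair is a no-op; linking a payload already bound to
#' a different patient is a conflict error.
#'
#' @param lookup a `bb_lookup`.
#' @param pu_patient_id source patient identifier.
#' @param payload barcode payload.
#' @return the updated lookup.
#' @export
link_payload <- function(lookup, pu_patient_id, payload) {
  stopifnot(inherits(lookup, "bb_lookup"))
  i <- match(payload, lookup$barcodes$payload)
  if (!is.na(i)) {
    if (lookup$barcodes$pu_patient_id[i] != pu_patient_id)
      dw_stop("dw_conflict_error",
              sprintf("payload already linked to a different patient: %s",
                      payload))
    return(lookup)
  }
  lookup$barcodes <- rbind(lookup$barcodes,
                           data.frame(payload = payload,
                                      pu_patient_id = pu_patient_id,
                                      stringsAsFactors = FALSE))
  lookup
}

#' Resolve a payload back to its patient id (gated)
#'
#' @param lookup a `bb_lookup`.
#' @param payload barcode payload.
#' @param authorized access flag; resolution without it is an authorization
#'   error.
#' @return the linked `pu_patient_id`.
#' @export
resolve_payload <- function(lookup, payload, authorized = FALSE) {
  if (!isTRUE(authorized))
    dw_stop("dw_authorization_error",
            "lookup resolution requires authorization")
  i <- match(payload, lookup$barcodes$payload)
  if (is.na(i))
    dw_stop("dw_not_found", sprintf("unknown payload: %s", payload))
  lookup$barcodes$pu_patient_id[i]
}

#' Get (or mint) the warehouse pseudonym for a source patient id
#'
#' Pseudonyms are `"PT-"` plus six random digits, unique within the lookup;
#' digits-only bodies cannot collide with alphabetic name substrings.
#'
#' @param lookup a `bb_lookup`.
#' @param pu_patient_id source patient identifier.
#' @param create mint a pseudonym when none exists yet.
#' @return list with the (possibly updated) `lookup` and the `warehouse_id`.
#' @export
pseudonym_for <- function(lookup, pu_patient_id, create = TRUE) {
  i <- match(pu_patient_id, lookup$pseudonyms$pu_patient_id)
  if (!is.na(i))
    return(list(lookup = lookup,
                warehouse_id = lookup$pseudonyms$warehouse_id[i]))
  if (!create)
    dw_stop("dw_not_found",
            sprintf("no pseudonym for patient %s", pu_patient_id))
  repeat {
    wid <- paste0("PT-", paste(sample(0:9, 6, replace = TRUE), collapse = ""))
    if (!wid %in% lookup$pseudonyms$warehouse_id) break
  }
  lookup$pseudonyms <- rbind(lookup$pseudonyms,
                             data.frame(pu_patient_id = pu_patient_id,
                                        warehouse_id = wid,
                                        stringsAsFactors = FALSE))
  list(lookup = lookup, warehouse_id = wid)
}

#' Save / load the lookup table in its own directory
#'
#' The lookup directory must be distinct from any warehouse or biobank
#' export directory; it is the one store that may contain source patient
#' identifiers.
#'
#' @param lookup a `bb_lookup`.
#' @param dir lookup directory.
#' @return `save_lookup`: the directory, invisibly; `load_lookup`: a
#'   `bb_lookup`.
#' @export
save_lookup <- function(lookup, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dw_write_table(lookup$barcodes, file.path(dir, "barcodes.tsv"))
  dw_write_table(lookup$pseudonyms, file.path(dir, "pseudonyms.tsv"))
  invisible(dir)
}

#' @rdname save_lookup
#' @export
load_lookup <- function(dir) {
  lk <- new_lookup()
  bfile <- file.path(dir, "barcodes.tsv")
  pfile <- file.path(dir, "pseudonyms.tsv")
  if (file.exists(bfile)) lk$barcodes <- dw_read_table(bfile)
  if (file.exists(pfile)) lk$pseudonyms <- dw_read_table(pfile)
  lk
}

#' Scan exported files for identifier leakage
#'
#' Reads every file and reports each occurrence of a length-4 substring of
#' any identifier field (case-normalized), plus any verbatim source patient
#' id.  An intact export yields a zero-row frame.
#'
#' @param paths files to scan (warehouse and biobank exports).
#' @param identifier_fields character vector of donor identifier values.
#' @param pu_patient_ids source patient ids that must never appear verbatim.
#' @return data frame with columns `file`, `needle`, `kind`.
#' @export
leak_scan <- function(paths, identifier_fields,
                      pu_patient_ids = character(0)) {
  grams <- unique(unlist(lapply(toupper(identifier_fields), function(f) {
    n <- nchar(f)
    if (is.na(f) || n < 4) return(character(0))
    vapply(seq_len(n - 3L), function(i) substring(f, i, i + 3L), character(1))
  })))
  hits <- list()
  for (p in paths) {
    txt <- toupper(paste(readLines(p, encoding = "UTF-8", warn = FALSE),
                         collapse = "\n"))
    for (g in grams)
      if (grepl(g, txt, fixed = TRUE))
        hits[[length(hits) + 1]] <- data.frame(file = p, needle = g,
                                               kind = "identifier_substring",
                                               stringsAsFactors = FALSE)
    for (id in toupper(pu_patient_ids))
      if (grepl(id, txt, fixed = TRUE))
        hits[[length(hits) + 1]] <- data.frame(file = p, needle = id,
                                               kind = "pu_patient_id",
                                               stringsAsFactors = FALSE)
  }
  if (length(hits)) do.call(rbind, hits)
  else data.frame(file = character(0), needle = character(0),
                  kind = character(0), stringsAsFactors = FALSE)
}
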