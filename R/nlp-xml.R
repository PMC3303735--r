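## XML serialization of extraction results.  Element names and order follow
## the structured-report schema shipped in inst/extdata/extraction_result.xsd:
## document > name, date, type, number, estrogens_receptors,
## progesterone_receptors, Ki67, c-erb_B2, grade, state, snomed (repeated
## code/name child pairs).  Absent optional fields are omitted.  The reader
## additionally tolerates the historical "progesterone_recoptors" spelling.

extraction_schema <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- xml2::read_xml(system.file("extdata",
                                           "extraction_result.xsd",
                                           package = "oncodw",
                                           mustWork = TRUE))
    cache
  }
})

num_chr <- function(x) {
  if (is.na(x)) NA_character_
  else format(x, scientific = FALSE, trim = TRUE)
}

#' Write an extraction result as an XML document
#'
#' @param result a valid [extraction_result()].
#' @param path optional file path; when given the document is also written
#'   there.
#' @return an `xml2::xml_document`, invisibly when `path` is given.
#' @export
write_extraction_xml <- function(result, path = NULL) {
  validate_extraction_result(result)
  doc <- xml2::xml_new_root("document")
  add <- function(tag, value) {
    if (!is.na(value) && nzchar(value))
      xml2::xml_add_child(doc, tag, value)
  }
  add("name", result$name)
  add("date", result$date)
  add("type", result$type)
  add("number", result$number)
  add("estrogens_receptors",
      if (!is.na(result$estrogens_receptors))
        num_chr(result$estrogens_receptors)
      else result$estrogens_receptors_status)
  add("progesterone_receptors",
      if (!is.na(result$progesterone_receptors))
        num_chr(result$progesterone_receptors)
      else result$progesterone_receptors_status)
  add("Ki67", num_chr(result$ki67))
  add("c-erb_B2", num_chr(result$c_erb_b2))
  add("grade", num_chr(result$grade))
  if (!is.null(result$state)) add("state", format_tnm(result$state))
  if (nrow(result$snomed)) {
    sn <- xml2::xml_add_child(doc, "snomed")
    for (i in seq_len(nrow(result$snomed))) {
      xml2::xml_add_child(sn, "code", result$snomed$code[i])
      xml2::xml_add_child(sn, "name", result$snomed$name[i])
    }
  }
  if (!is.null(path)) {
    xml2::write_xml(doc, path)
    return(invisible(doc))
  }
  doc
}

xml_child_text <- function(doc, tags) {
  for (tag in tags) {
    node <- xml2::xml_find_first(doc, paste0("./", tag))
    if (!inherits(node, "xml_missing")) return(xml2::xml_text(node))
  }
  NA_character_
}

#' Read an extraction result from an XML document
#'
#' The document is validated against the packaged schema before parsing;
#' schema violations raise a validation error carrying the libxml element
#' messages.  `read_extraction_xml(write_extraction_xml(r))` is the identity
#' on valid records.
#'
#' @param x a file path, an XML string, or an `xml2::xml_document`.
#' @param validate validate against the packaged XSD (default `TRUE`).
#' @return an [extraction_result()].
#' @export
read_extraction_xml <- function(x, validate = TRUE) {
  doc <- if (inherits(x, "xml_document")) x else xml2::read_xml(x)
  if (validate) {
    ok <- xml2::xml_validate(doc, extraction_schema())
    if (!ok)
      dw_stop("dw_xml_validation",
              paste("XML schema violation:",
                    paste(attr(ok, "errors"), collapse = "; ")),
              errors = attr(ok, "errors"))
  }
  root <- xml2::xml_root(doc)
  receptor <- function(tags) {
    raw <- xml_child_text(root, tags)
    if (is.na(raw)) list(value = NA_real_, status = NA_character_)
    else if (grepl("^(positive|negative)$", raw))
      list(value = NA_real_, status = raw)
    else list(value = as.numeric(raw), status = NA_character_)
  }
  er <- receptor("estrogens_receptors")
  pr <- receptor(c("progesterone_receptors", "progesterone_recoptors"))
  state_raw <- xml_child_text(root, "state")
  sn_node <- xml2::xml_find_first(root, "./snomed")
  snomed <- if (inherits(sn_node, "xml_missing"))
    data.frame(code = character(0), name = character(0),
               stringsAsFactors = FALSE)
  else data.frame(
    code = xml2::xml_text(xml2::xml_find_all(sn_node, "./code")),
    name = xml2::xml_text(xml2::xml_find_all(sn_node, "./name")),
    stringsAsFactors = FALSE)
  extraction_result(
    name = xml_child_text(root, "name"),
    date = xml_child_text(root, "date"),
    type = xml_child_text(root, "type"),
    number = xml_child_text(root, "number"),
    estrogens_receptors = er$value,
    estrogens_receptors_status = er$status,
    progesterone_receptors = pr$value,
    progesterone_receptors_status = pr$status,
    ki67 = as.numeric(xml_child_text(root, "Ki67")),
    c_erb_b2 = as.integer(xml_child_text(root, "c-erb_B2")),
    grade = as.integer(xml_child_text(root, "grade")),
    state = if (is.na(state_raw)) NULL else extract_tnm(state_raw),
    snomed = snomed)
}
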