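## Concept hierarchy construction.  A term tree (the desk-scale stand-in for a
## subtree extracted from a pre-defined terminology service) is turned into
## concept-dimension rows whose backslash paths drive prefix-based query
## expansion.  The packaged fixture is a synthetic ~40-term lexicon of breast
## lesion morphology under a "Neoplasm and hamartoma" root; its codes follow
## the axis-letter + 5 digit surface form of SNOMED morphology codes but are
## lexicon entries, not assertions about any terminology release.

#' Construct a term-tree node
#'
#' @param term_id unique identifier (kept as `concept_code` downstream).
#' @param name preferred name (becomes a path segment downstream).
#' @param children ordered list of child `term_node`s.
#' @return a `term_node`.
#' @export
term_node <- function(term_id, name, children = list()) {
  stopifnot(is.character(term_id), nzchar(term_id), is.character(name))
  structure(list(term_id = term_id, name = name, children = children),
            class = "term_node")
}

#' Construct an ontology source (a named term tree)
#'
#' @param source_name human-readable name of the terminology subset.
#' @param root the root [term_node()].
#' @return an `ontology_source`.
#' @export
ontology_source <- function(source_name, root) {
  stopifnot(inherits(root, "term_node"))
  ids <- tree_ids(root)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    dw_stop("dw_value_error",
            sprintf("duplicate term_id(s) in tree: %s",
                    paste(unique(dup), collapse = ", ")))
  structure(list(source_name = source_name, root = root),
            class = "ontology_source")
}

tree_ids <- function(node) {
  c(node$term_id, unlist(lapply(node$children, tree_ids), use.names = FALSE))
}

tree_size <- function(node) length(tree_ids(node))

#' Read a term tree from an indentation-nested text file
#'
#' Format: optional `# source: <name>` header; one term per line as
#' `term_id<TAB>name`, nesting expressed by two spaces of indentation per
#' level; the first term is the root.
#'
#' @param path file path.
#' @return an [ontology_source()].
#' @export
read_term_tree <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  src_name <- basename(path)
  hdr <- grepl("^#", lines)
  m <- regmatches(lines[hdr], regexec("^#\\s*source:\\s*(.+)$", lines[hdr]))
  for (mm in m) if (length(mm) == 2) src_name <- trimws(mm[2])
  lines <- lines[!hdr & nzchar(trimws(lines))]
  if (!length(lines)) dw_stop("dw_parse_error", "empty term-tree file")
  indent <- nchar(sub("^( *).*$", "\\1", lines))
  if (any(indent %% 2 != 0))
    dw_stop("dw_parse_error", "term-tree indentation must be multiples of 2")
  depth <- indent %/% 2
  parts <- strsplit(trimws(lines), "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) != 2
  if (any(bad))
    dw_stop("dw_parse_error",
            sprintf("term-tree line without 'id<TAB>name': %s",
                    lines[bad][1]))
  build <- function(i, d) {
    node <- term_node(parts[[i]][1], parts[[i]][2])
    j <- i + 1
    while (j <= length(lines) && depth[j] > d) {
      if (depth[j] == d + 1) {
        child <- build(j, d + 1)
        node$children <- c(node$children, list(child$node))
        j <- child$nxt
      } else dw_stop("dw_parse_error",
                     sprintf("indentation jump at line: %s", lines[j]))
    }
    list(node = node, nxt = j)
  }
  if (depth[1] != 0) dw_stop("dw_parse_error", "root term must be unindented")
  res <- build(1, 0)
  if (res$nxt <= length(lines))
    dw_stop("dw_parse_error", "multiple root terms in term-tree file")
  ontology_source(src_name, res$node)
}

#' Read a subclass hierarchy from an OWL (RDF/XML) file
#'
#' Minimal reader for `owl:Class` declarations with `rdfs:label` and single
#' `rdfs:subClassOf` resource references, as produced by ontology subtree
#' extraction services.  Classes without a parent inside the file become the
#' root; exactly one such class is required.
#'
#' @param path OWL RDF/XML file.
#' @return an [ontology_source()].
#' @export
read_owl_tree <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(owl = "http://www.w3.org/2002/07/owl#",
          rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
          rdfs = "http://www.w3.org/2000/01/rdf-schema#")
  classes <- xml2::xml_find_all(doc, "//owl:Class[@rdf:about]", ns)
  if (!length(classes)) dw_stop("dw_parse_error", "no owl:Class found")
  frag <- function(uri) sub("^.*[#/]", "", uri)
  ids <- frag(xml2::xml_attr(classes, "about"))
  labels <- vapply(classes, function(cl) {
    lab <- xml2::xml_find_first(cl, "./rdfs:label", ns)
    if (inherits(lab, "xml_missing")) NA_character_ else xml2::xml_text(lab)
  }, character(1))
  labels[is.na(labels)] <- ids[is.na(labels)]
  parents <- vapply(classes, function(cl) {
    sup <- xml2::xml_find_first(cl, "./rdfs:subClassOf[@rdf:resource]", ns)
    if (inherits(sup, "xml_missing")) NA_character_
    else frag(xml2::xml_attr(sup, "resource"))
  }, character(1))
  parents[!parents %in% ids] <- NA_character_
  roots <- which(is.na(parents))
  if (length(roots) != 1)
    dw_stop("dw_parse_error",
            sprintf("expected exactly one root class, found %d",
                    length(roots)))
  build <- function(i) {
    kids <- which(!is.na(parents) & parents == ids[i])
    term_node(ids[i], labels[i], lapply(kids, build))
  }
  ontology_source(basename(path), build(roots))
}

#' Extract the subtree rooted at a term
#'
#' Walks the tree and returns the branch below (and including) `root_id`,
#' descendants and sibling order preserved — the local analogue of a
#' "view extraction" call against a terminology service.
#'
#' @param source an [ontology_source()] or a [term_node()].
#' @param root_id the term to root the view at.
#' @return a [term_node()].
#' @export
extract_view <- function(source, root_id) {
  root <- if (inherits(source, "ontology_source")) source$root else source
  stopifnot(inherits(root, "term_node"))
  find <- function(node) {
    if (node$term_id == root_id) return(node)
    for (ch in node$children) {
      hit <- find(ch)
      if (!is.null(hit)) return(hit)
    }
    NULL
  }
  hit <- find(root)
  if (is.null(hit))
    dw_stop("dw_not_found", sprintf("term_id '%s' not found in tree", root_id))
  hit
}

#' Convert a term subtree into concept-dimension rows
#'
#' Each node becomes one concept: `concept_path` is `base_path` followed by
#' the names of the node's ancestors within the subtree and the node's own
#' name; `level` is the number of path segments.  Stub rows for the segments
#' of `base_path` itself are included so the parent-present invariant holds
#' for the returned set in isolation.  Node names form the path segments
#' (term ids are kept as `concept_code`), so duplicate sibling names are
#' rejected rather than silently disambiguated.
#'
#' @param subtree a [term_node()].
#' @param base_path backslash-delimited path the subtree hangs under,
#'   e.g. `"\\SNOMED\\"`.
#' @param source concept source tag, one of SNOMED, TNM, BIOMARKER, BIOBANK,
#'   DEMOGRAPHIC, VISIT, OTHER.
#' @return data frame of concept rows.
#' @export
build_concepts <- function(subtree, base_path, source = "SNOMED") {
  stopifnot(inherits(subtree, "term_node"))
  if (!well_formed_path(base_path))
    dw_stop("dw_value_error", sprintf("malformed base path '%s'", base_path))
  if (!source %in% CONCEPT_SOURCES)
    dw_stop("dw_value_error", sprintf("unknown concept source '%s'", source))
  rows <- list()
  walk <- function(node, prefix) {
    nms <- vapply(node$children, `[[`, character(1), "name")
    if (anyDuplicated(nms))
      dw_stop("dw_duplicate_sibling",
              sprintf("duplicate sibling name '%s' under '%s'",
                      nms[duplicated(nms)][1], node$name))
    path <- paste0(prefix, node$name, "\\")
    rows[[length(rows) + 1]] <<- data.frame(
      concept_code = node$term_id, concept_path = path, name = node$name,
      level = path_level(path), source = source, stringsAsFactors = FALSE)
    for (ch in node$children) walk(ch, path)
  }
  walk(subtree, base_path)
  out <- do.call(rbind, rows)
  rbind(base_path_stubs(base_path, source), out)
}

base_path_stubs <- function(base_path, source) {
  segs <- path_segments(base_path)
  paths <- vapply(seq_along(segs), function(i)
    paste0("\\", paste(segs[seq_len(i)], collapse = "\\"), "\\"), character(1))
  data.frame(concept_code = paste0("DIM:", toupper(gsub("[^A-Za-z0-9]+", "_",
                                                        segs))),
             concept_path = paths, name = segs,
             level = seq_along(segs), source = source,
             stringsAsFactors = FALSE)
}

#' Concepts at or below a path
#'
#' Returns every concept whose path has `path` as a segment-aligned prefix,
#' including the concept at `path` itself; an unknown path yields a zero-row
#' frame.
#'
#' @param concepts concept data frame.
#' @param path backslash-delimited path.
#' @return subset of `concepts`.
#' @export
concept_descendants <- function(concepts, path) {
  if (!well_formed_path(path))
    dw_stop("dw_value_error", sprintf("malformed concept path '%s'", path))
  concepts[path_has_prefix(concepts$concept_path, path), , drop = FALSE]
}

#' The packaged breast-lesion morphology term tree
#'
#' @return an [ontology_source()] with a "Neoplasm and hamartoma" root.
#' @export
default_term_tree <- function() {
  read_term_tree(system.file("extdata", "morphology_tree.txt",
                             package = "oncodw", mustWork = TRUE))
}

#' SNOMED-style code lexicon derived from a term tree
#'
#' @param source an [ontology_source()]; defaults to the packaged tree.
#' @return named character vector, `code -> preferred name`.
#' @export
snomed_lexicon <- function(source = default_term_tree()) {
  collect <- function(node)
    c(setNames(node$name, node$term_id),
      unlist(lapply(node$children, collect)))
  collect(source$root)
}
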