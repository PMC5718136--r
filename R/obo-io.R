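# OBO flat-file subset reader/writer.
#
# Supported stanza lines: id, name, is_a (with optional "! label" comment),
# property_value: severity <level> / laterality <side>, and is_obsolete.
# This subset carries everything the engine reasons over: the named-class
# is_a skeleton plus the severity/laterality qualifiers.

#' Load a phenotype ontology from an OBO flat file
#'
#' Parses the OBO-1.4 subset used as the package's native ontology format
#' (`[Term]` stanzas with `id`, `name`, `is_a` and severity/laterality
#' `property_value` lines).  Obsolete terms are excluded from the graph.  The
#' result is validated: unique ids, no dangling parents, acyclic, single
#' root.
#'
#' @param path path to an OBO file.
#' @return a [phenotype_ontology()].
#' @seealso [write_obo()], [sara_ontology()]
#' @export
load_obo <- function(path) {
  if (!file.exists(path)) stop("OBO file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\\s+$", "", lines)

  term_starts <- which(lines == "[Term]")
  other_stanzas <- grepl("^\\[", lines) & lines != "[Term]"
  bounds <- c(term_starts, which(other_stanzas), length(lines) + 1L)

  classes <- list()
  for (s in term_starts) {
    end <- min(bounds[bounds > s]) - 1L
    block <- lines[seq(s + 1L, max(s + 1L, end))]
    block <- block[nzchar(block) & !grepl("^!", block)]
    cl <- .parse_term_stanza(block, line = s)
    if (!cl$obsolete) classes[[length(classes) + 1L]] <- cl
  }
  if (length(classes) == 0) stop("no [Term] stanzas found in ", path)
  phenotype_ontology(classes)
}

.parse_term_stanza <- function(block, line) {
  id <- NULL; name <- NULL; parents <- character()
  severity <- NA_character_; laterality <- NA_character_; obsolete <- FALSE
  for (ln in block) {
    if (!grepl("^[a-z_]+:", ln)) {
      stop("malformed OBO line near line ", line, ": '", ln, "'")
    }
    key <- sub(":.*$", "", ln)
    val <- sub("^[a-z_]+:\\s*", "", ln)
    if (key == "id") id <- val
    else if (key == "name") name <- val
    else if (key == "is_a") parents <- c(parents, sub("\\s*!.*$", "", val))
    else if (key == "is_obsolete") obsolete <- tolower(val) %in% c("true", "1")
    else if (key == "property_value") {
      pv <- strsplit(val, "\\s+")[[1]]
      if (length(pv) >= 2) {
        pval <- gsub('"', "", pv[2])
        if (pv[1] == "severity") severity <- pval
        if (pv[1] == "laterality") laterality <- pval
      }
    }
    # other keys (def, comment, xref, ...) are tolerated and ignored
  }
  if (is.null(id)) stop("OBO [Term] stanza near line ", line, " lacks an id")
  onto_class(id, label = if (is.null(name)) id else name, parents = parents,
             severity = severity, laterality = laterality,
             obsolete = obsolete)
}

#' Write a phenotype ontology as an OBO flat file
#'
#' Deterministic serialization (stanzas sorted by class id) so that ontology
#' fixtures are stable across runs and `load_obo(write_obo(O))` reproduces
#' the identical class and edge sets.
#'
#' @param ont a [phenotype_ontology()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(ont, path) {
  out <- c("format-version: 1.4",
           paste0("ontology: ", ont$root), "")
  for (id in sort(names(ont$classes))) {
    cl <- ont$classes[[id]]
    stanza <- c("[Term]",
                paste0("id: ", cl$id),
                paste0("name: ", cl$label))
    for (p in sort(cl$parents)) {
      stanza <- c(stanza, paste0("is_a: ", p, " ! ", ont$classes[[p]]$label))
    }
    if (!is.na(cl$severity)) {
      stanza <- c(stanza, paste0("property_value: severity ", cl$severity))
    }
    if (!is.na(cl$laterality)) {
      stanza <- c(stanza, paste0("property_value: laterality ", cl$laterality))
    }
    out <- c(out, stanza, "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Import the asserted subclass hierarchy of an OWL/XML file
#'
#' Reads named classes (`owl:Class` with an IRI) and asserted
#' `rdfs:subClassOf` axioms between named classes.  Anonymous superclass
#' expressions (e.g. `owl:Restriction`) are skipped with a warning giving
#' their count: the interpretation engine only needs named-class subsumption.
#' Class ids are the IRI fragments.
#'
#' @param path path to an OWL (RDF/XML) file.
#' @return a [phenotype_ontology()] over the named-class is_a skeleton.
#' @export
import_owl_subclass_hierarchy <- function(path) {
  if (!file.exists(path)) stop("OWL file not found: ", path)
  doc <- xml2::read_xml(path)
  ns <- c(owl  = "http://www.w3.org/2002/07/owl#",
          rdf  = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
          rdfs = "http://www.w3.org/2000/01/rdf-schema#")
  cls_nodes <- xml2::xml_find_all(doc, "//owl:Class[@rdf:about]", ns)
  if (length(cls_nodes) == 0) stop("no named owl:Class elements in ", path)

  frag <- function(iri) sub("^.*[#/]", "", iri)
  skipped <- 0L
  classes <- list()
  for (node in cls_nodes) {
    id <- frag(xml2::xml_attr(node, "about"))
    lab_node <- xml2::xml_find_first(node, "./rdfs:label", ns)
    label <- if (inherits(lab_node, "xml_missing")) id else
      xml2::xml_text(lab_node)
    parents <- character()
    for (sc in xml2::xml_find_all(node, "./rdfs:subClassOf", ns)) {
      res <- xml2::xml_attr(sc, "resource")
      if (!is.na(res)) {
        parents <- c(parents, frag(res))
      } else {
        named <- xml2::xml_find_first(sc, "./owl:Class[@rdf:about]", ns)
        if (!inherits(named, "xml_missing")) {
          parents <- c(parents, frag(xml2::xml_attr(named, "about")))
        } else {
          skipped <- skipped + 1L
        }
      }
    }
    sev_node <- xml2::xml_find_first(node, "./*[local-name() = 'severity']")
    severity <- if (inherits(sev_node, "xml_missing")) NA_character_ else
      xml2::xml_text(sev_node)
    classes[[length(classes) + 1L]] <-
      onto_class(id, label = label, parents = parents, severity = severity)
  }
  if (skipped > 0) {
    warning("skipped ", skipped,
            " non-named subClassOf axiom(s) (anonymous class expressions)")
  }
  phenotype_ontology(classes)
}

#' Export an ontology as a node-link list
#'
#' Shape suitable for `jsonlite::toJSON` and d3-style force layouts: one row
#' per class and one row per is_a edge (child -> parent).
#'
#' @param ont a [phenotype_ontology()].
#' @return list with data frames `nodes` (id, label, severity) and
#'   `links` (source, target).
#' @export
as_node_link <- function(ont) {
  ids <- sort(names(ont$classes))
  nodes <- data.frame(
    id = ids,
    label = vapply(ont$classes[ids], function(x) x$label, character(1)),
    severity = vapply(ont$classes[ids], function(x) x$severity, character(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  edges <- do.call(rbind, lapply(ont$classes[ids], function(cl) {
    if (length(cl$parents) == 0) return(NULL)
    data.frame(source = cl$id, target = sort(cl$parents),
               stringsAsFactors = FALSE)
  }))
  if (is.null(edges)) {
    edges <- data.frame(source = character(), target = character(),
                        stringsAsFactors = FALSE)
  }
  rownames(edges) <- NULL
  list(nodes = nodes, links = edges)
}

#' Export an ontology as a Graphviz DOT digraph
#'
#' @param ont a [phenotype_ontology()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dot <- function(ont, path) {
  nl <- as_node_link(ont)
  lines <- c("digraph phenotype_ontology {",
             "  rankdir=BT;",
             sprintf('  "%s" [label="%s"];', nl$nodes$id, nl$nodes$label))
  if (nrow(nl$links) > 0) {
    lines <- c(lines,
               sprintf('  "%s" -> "%s";', nl$links$source, nl$links$target))
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}
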