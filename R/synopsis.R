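# Clinical synopsis: translate severity findings into asserted ontology
# classes, infer the subsumption closure, summarize the three clinical
# dimensions (midline/truncal ataxia, speech, appendicular ataxia per side),
# and render the textual report and machine-readable exports.

#' Infer the phenotype closure from severity findings
#'
#' Non-absent findings are asserted as ontology individuals: the severity
#' subclass (`<severity>_<class>`) when it exists in the ontology, otherwise
#' the bound class itself (terminal classes such as `abasia` carry no
#' severity subclasses).  The result is the full subsumption closure via
#' [classify_individual()] -- e.g. an asserted `abasia` entails `gait_ataxia`
#' and `truncal_ataxia`.
#'
#' @param ont a [phenotype_ontology()].
#' @param findings list of findings from [apply_severity_rules()].
#' @return sorted character vector of inferred class ids (empty when all
#'   findings are absent).
#' @export
infer_phenotypes <- function(ont, findings) {
  asserted <- character()
  for (f in findings) {
    if (identical(f$severity, "absent")) next
    if (!f$onto_class %in% class_ids(ont)) {
      stop("finding references unresolved ontology class: ", f$onto_class)
    }
    sev_id <- paste0(f$severity, "_", f$onto_class)
    asserted <- c(asserted,
                  if (sev_id %in% class_ids(ont)) sev_id else f$onto_class)
  }
  classify_individual(ont, unique(asserted))
}

.max_severity <- function(severities) {
  if (length(severities) == 0) return("absent")
  ranks <- severity_rank(severities)
  c("absent", SEVERITY_LEVELS)[max(ranks) + 1L]
}

#' Compose the clinical synopsis
#'
#' Summarizes the phenotypic features accompanying the cerebellar syndrome,
#' one row per clinical dimension: midline (truncal) ataxia from the gait /
#' stance / sitting findings, speech impairment, and appendicular ataxia
#' separately per side.  Each feature's severity is the maximum severity
#' rank of its member findings (a feature is absent iff all members are
#' absent).  Asymmetry of the appendicular findings is flagged when the two
#' sides' severity ranks differ by at least `asymmetry_threshold`.
#'
#' @param eval an `evaluation_record` (the `findings` element is used).
#' @param ont a [phenotype_ontology()].
#' @param asymmetry_threshold minimum left/right severity-rank difference to
#'   flag an asymmetrical cerebellar syndrome (default 2).
#' @return an object of class `sara_synopsis`: a list with a `features` data
#'   frame (feature, onto_class, laterality, present, severity) and an
#'   `asymmetry` flag.
#' @export
build_synopsis <- function(eval, ont, asymmetry_threshold = 2L) {
  findings <- eval$findings
  cluster_of <- function(cl) Filter(function(f) f$cluster == cl, findings)
  sev_of <- function(fs) .max_severity(vapply(fs, function(f) f$severity,
                                              character(1)))
  midline <- sev_of(cluster_of("gait_and_balance"))
  speech <- sev_of(cluster_of("speech_disturbance"))
  limb <- cluster_of("limb_coordination")
  right <- sev_of(Filter(function(f) identical(f$side, "right"), limb))
  left <- sev_of(Filter(function(f) identical(f$side, "left"), limb))

  features <- data.frame(
    feature = c("midline ataxia", "speech impairment",
                "appendicular ataxia (right)", "appendicular ataxia (left)"),
    onto_class = c("truncal_ataxia", "dysarthria",
                   "appendicular_ataxia", "appendicular_ataxia"),
    laterality = c(NA, NA, "right", "left"),
    severity = c(midline, speech, right, left),
    stringsAsFactors = FALSE
  )
  features$present <- features$severity != "absent"
  asym <- abs(severity_rank(left) - severity_rank(right)) >=
    asymmetry_threshold
  structure(list(features = features, asymmetry = asym,
                 asymmetry_threshold = as.integer(asymmetry_threshold)),
            class = "sara_synopsis")
}

#' @export
print.sara_synopsis <- function(x, ...) {
  print(x$features[, c("feature", "severity", "present")], row.names = FALSE)
  if (isTRUE(x$asymmetry)) cat("asymmetrical appendicular involvement\n")
  invisible(x)
}

#' Render the textual patient report
#'
#' Deterministic plain-text summary: the cerebellar-syndrome assessment
#' sentence, the synopsis features with their severities, and the inferred
#' phenotypic abnormalities.  A pure function of the evaluation record:
#' identical records render byte-identical reports.
#'
#' @param eval an `evaluation_record` with `assessment`, `synopsis` and
#'   `inferred` populated.
#' @return a single character string.
#' @export
render_report <- function(eval) {
  a <- eval$assessment
  lines <- c(
    paste0("SARA interpretation report for patient ", eval$patient_id),
    if (!is.na(eval$date)) paste0("Assessment date: ", eval$date),
    sprintf("Total SARA score: %g / 40", a$total),
    if (a$category == "absent")
      "Cerebellar syndrome: absent."
    else
      sprintf("Cerebellar syndrome: present, %s.", a$category),
    ""
  )
  feats <- eval$synopsis$features
  present <- feats[feats$present, , drop = FALSE]
  if (nrow(present) == 0) {
    lines <- c(lines, "No phenotypic abnormalities were inferred.")
  } else {
    lines <- c(lines, "Phenotype synopsis:",
               sprintf("  - %s: %s", present$feature, present$severity))
    if (isTRUE(eval$synopsis$asymmetry)) {
      lines <- c(lines,
                 "  - asymmetrical involvement of the two sides")
    }
    lines <- c(lines, "",
               "Inferred phenotypic abnormalities:",
               paste0("  ", sort(eval$inferred)))
  }
  paste(lines, collapse = "\n")
}

#' @export
print.evaluation_record <- function(x, ...) {
  cat(x$report, "\n")
  invisible(x)
}

#' Export an evaluation record as XML
#'
#' Serializes the complete interpretation of one patient (derived scores,
#' findings, syndrome assessment, inferred classes, synopsis, report) for
#' interoperable exchange.  [evaluation_from_xml()] parses the payload back
#' into an equal `evaluation_record`.
#'
#' @param eval an `evaluation_record`.
#' @param path optional output path; when given the document is written
#'   there.
#' @return an `xml_document`, invisibly if `path` is given.
#' @export
evaluation_to_xml <- function(eval, path = NULL) {
  doc <- xml2::xml_new_root("sara_evaluation")
  xml2::xml_set_attr(doc, "patient_id", eval$patient_id)
  if (!is.na(eval$date)) xml2::xml_set_attr(doc, "date", eval$date)

  der <- xml2::xml_add_child(doc, "derived_scores",
                             total = format(eval$derived$total))
  for (item in names(eval$derived$means)) {
    xml2::xml_add_child(der, "mean", item = item,
                        value = format(eval$derived$means[[item]]))
  }
  fnode <- xml2::xml_add_child(doc, "findings")
  for (f in eval$findings) {
    xml2::xml_add_child(fnode, "finding", element = f$element, item = f$item,
                        side = if (is.na(f$side)) "none" else f$side,
                        score = format(f$score), class = f$onto_class,
                        severity = f$severity, cluster = f$cluster,
                        rule = f$rule_id)
  }
  xml2::xml_add_child(doc, "assessment",
                      category = eval$assessment$category,
                      total = format(eval$assessment$total),
                      rule = eval$assessment$rule_id)
  inode <- xml2::xml_add_child(doc, "inferred")
  for (cl in sort(eval$inferred)) {
    xml2::xml_add_child(inode, "class", id = cl)
  }
  snode <- xml2::xml_add_child(
    doc, "synopsis",
    asymmetry = tolower(as.character(eval$synopsis$asymmetry)),
    asymmetry_threshold = format(eval$synopsis$asymmetry_threshold)
  )
  for (i in seq_len(nrow(eval$synopsis$features))) {
    r <- eval$synopsis$features[i, ]
    xml2::xml_add_child(snode, "feature", name = r$feature,
                        class = r$onto_class,
                        laterality = if (is.na(r$laterality)) "none" else
                          r$laterality,
                        severity = r$severity,
                        present = tolower(as.character(r$present)))
  }
  frnode <- xml2::xml_add_child(doc, "fired_rules")
  for (r in eval$fired_rules) {
    xml2::xml_add_child(frnode, "rule", id = r)
  }
  rnode <- xml2::xml_add_child(doc, "report")
  xml2::xml_set_text(rnode, eval$report)
  if (!is.null(path)) {
    xml2::write_xml(doc, path)
    return(invisible(doc))
  }
  doc
}

#' Parse an evaluation record back from its XML export
#'
#' @param x an `xml_document` or path to an XML file produced by
#'   [evaluation_to_xml()].
#' @return an `evaluation_record` equal to the exported one.
#' @export
evaluation_from_xml <- function(x) {
  doc <- if (inherits(x, "xml_document")) x else xml2::read_xml(x)
  root <- xml2::xml_root(doc)
  attr_of <- function(node, a) xml2::xml_attr(node, a)
  na_if_none <- function(v) if (identical(v, "none")) NA_character_ else v

  der_node <- xml2::xml_find_first(root, "./derived_scores")
  means <- vapply(xml2::xml_find_all(der_node, "./mean"),
                  function(n) as.numeric(attr_of(n, "value")), numeric(1))
  names(means) <- vapply(xml2::xml_find_all(der_node, "./mean"),
                         function(n) attr_of(n, "item"), character(1))
  derived <- structure(
    list(means = means, total = as.numeric(attr_of(der_node, "total"))),
    class = "derived_scores"
  )
  findings <- lapply(xml2::xml_find_all(root, "./findings/finding"),
                     function(n) {
    side <- na_if_none(attr_of(n, "side"))
    list(element = attr_of(n, "element"), item = attr_of(n, "item"),
         side = side, score = as.integer(attr_of(n, "score")),
         onto_class = attr_of(n, "class"), severity = attr_of(n, "severity"),
         laterality = side, cluster = attr_of(n, "cluster"),
         rule_id = attr_of(n, "rule"))
  })
  a_node <- xml2::xml_find_first(root, "./assessment")
  assessment <- structure(
    list(category = attr_of(a_node, "category"),
         total = as.numeric(attr_of(a_node, "total")),
         rule_id = attr_of(a_node, "rule")),
    class = "syndrome_assessment"
  )
  inferred <- vapply(xml2::xml_find_all(root, "./inferred/class"),
                     function(n) attr_of(n, "id"), character(1))
  s_node <- xml2::xml_find_first(root, "./synopsis")
  feat_nodes <- xml2::xml_find_all(s_node, "./feature")
  features <- data.frame(
    feature = vapply(feat_nodes, attr_of, character(1), a = "name"),
    onto_class = vapply(feat_nodes, attr_of, character(1), a = "class"),
    laterality = vapply(feat_nodes, function(n)
      na_if_none(attr_of(n, "laterality")), character(1)),
    severity = vapply(feat_nodes, attr_of, character(1), a = "severity"),
    stringsAsFactors = FALSE
  )
  features$present <- vapply(feat_nodes, function(n)
    identical(attr_of(n, "present"), "true"), logical(1))
  synopsis <- structure(
    list(features = features,
         asymmetry = identical(attr_of(s_node, "asymmetry"), "true"),
         asymmetry_threshold =
           as.integer(attr_of(s_node, "asymmetry_threshold"))),
    class = "sara_synopsis"
  )
  structure(
    list(patient_id = attr_of(root, "patient_id"),
         date = attr_of(root, "date"), derived = derived,
         findings = findings, assessment = assessment,
         inferred = sort(inferred), synopsis = synopsis,
         report = xml2::xml_text(xml2::xml_find_first(root, "./report")),
         fired_rules = vapply(xml2::xml_find_all(root, "./fired_rules/rule"),
                              function(n) xml2::xml_attr(n, "id"),
                              character(1))),
    class = "evaluation_record"
  )
}

#' Export an evaluation record as a JSON payload
#'
#' @param eval an `evaluation_record`.
#' @param path optional output path.
#' @return JSON string (class `json`), invisibly if `path` is given.
#' @export
evaluation_to_json <- function(eval, path = NULL) {
  payload <- list(
    patient_id = eval$patient_id, date = eval$date,
    derived = list(means = as.list(eval$derived$means),
                   total = eval$derived$total),
    findings = lapply(eval$findings, function(f) f[c(
      "element", "item", "side", "score", "onto_class", "severity",
      "cluster", "rule_id")]),
    assessment = list(category = eval$assessment$category,
                      total = eval$assessment$total),
    inferred = as.list(sort(eval$inferred)),
    synopsis = list(features = eval$synopsis$features,
                    asymmetry = eval$synopsis$asymmetry),
    fired_rules = as.list(eval$fired_rules)
  )
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, pretty = TRUE,
                         na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Node-link graph of the inferred phenotypes
#'
#' The inferred closure with its is_a edges, for graph display of a
#' patient's phenotypic abnormalities.
#'
#' @param eval an `evaluation_record` with a non-empty `inferred` set.
#' @param ont the [phenotype_ontology()] the evaluation was made against.
#' @return a node-link list as from [as_node_link()]; `NULL` when nothing
#'   was inferred.
#' @export
evaluation_graph <- function(eval, ont) {
  if (length(eval$inferred) == 0) return(NULL)
  as_node_link(extract_module(ont, eval$inferred))
}
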