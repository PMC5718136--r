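# Phenotype ontology container and subsumption machinery.
#
# The ontology is a rooted directed acyclic graph of named classes connected
# by is_a edges (child -> parent).  All reasoning the interpretation engine
# needs -- ancestor closure, module extraction, individual classification --
# is named-class subsumption over this graph.

#' Severity levels recognized by the ontology and the rule base
#'
#' The five graded levels, ordered from least to most severe.  The rank
#' ordering used throughout the package is
#' `absent < borderline < mild < moderate < severe < profound`;
#' `absent` is a finding state, not an ontology qualifier.
#'
#' @export
SEVERITY_LEVELS <- c("borderline", "mild", "moderate", "severe", "profound")

#' @rdname SEVERITY_LEVELS
#' @export
LATERALITY_VALUES <- c("left", "right", "bilateral")

#' Numeric rank of a severity label
#'
#' @param severity character vector of labels from
#'   `c("absent", SEVERITY_LEVELS)`.
#' @return integer vector; `absent` is 0, `profound` is 5.
#' @export
severity_rank <- function(severity) {
  ranks <- c(absent = 0L, borderline = 1L, mild = 2L, moderate = 3L,
             severe = 4L, profound = 5L)
  unknown <- setdiff(severity, c(names(ranks), NA))
  if (length(unknown) > 0) {
    stop("unknown severity level(s): ", paste(unknown, collapse = ", "))
  }
  unname(ranks[severity])
}

#' Create a phenotype ontology class record
#'
#' @param id class identifier (unique within an ontology).
#' @param label human-readable name; defaults to the id.
#' @param parents character vector of parent class identifiers (is_a).
#' @param severity optional severity qualifier, one of [SEVERITY_LEVELS].
#' @param laterality optional side qualifier, one of [LATERALITY_VALUES].
#' @param obsolete logical flag; obsolete classes are dropped on load.
#' @return a list of class `onto_class`.
#' @export
onto_class <- function(id, label = id, parents = character(),
                       severity = NA_character_, laterality = NA_character_,
                       obsolete = FALSE) {
  stopifnot(is.character(id), length(id) == 1, nzchar(id))
  if (!is.na(severity) && !severity %in% SEVERITY_LEVELS) {
    stop("invalid severity '", severity, "' for class '", id, "'")
  }
  if (!is.na(laterality) && !laterality %in% LATERALITY_VALUES) {
    stop("invalid laterality '", laterality, "' for class '", id, "'")
  }
  structure(
    list(id = id, label = label, parents = unique(as.character(parents)),
         severity = severity, laterality = laterality,
         obsolete = isTRUE(obsolete)),
    class = "onto_class"
  )
}

#' Build a validated phenotype ontology
#'
#' Assembles [onto_class()] records into a rooted is_a DAG and validates it:
#' ids must be unique, every parent reference must resolve, the graph must be
#' acyclic, and exactly one class (the root) may lack parents, so every class
#' reaches the root.
#'
#' @param classes list of [onto_class()] records.
#' @param root identifier of the root class; if `NULL`, the unique parentless
#'   class is taken as root.
#' @return an object of class `phenotype_ontology`.
#' @export
phenotype_ontology <- function(classes, root = NULL) {
  if (length(classes) == 0) stop("ontology must contain at least one class")
  ids <- vapply(classes, function(x) x$id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate class id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(classes) <- ids

  dangling <- unique(unlist(lapply(classes, function(x) {
    setdiff(x$parents, ids)
  })))
  if (length(dangling) > 0) {
    stop("dangling parent reference(s): ", paste(dangling, collapse = ", "))
  }

  cyc <- .find_cycle_members(classes)
  if (length(cyc) > 0) {
    stop("is_a cycle involving class(es): ", paste(sort(cyc), collapse = ", "))
  }

  parentless <- ids[vapply(classes, function(x) length(x$parents) == 0,
                           logical(1))]
  if (is.null(root)) {
    if (length(parentless) != 1) {
      stop("cannot infer root: ", length(parentless),
           " parentless classes (", paste(parentless, collapse = ", "), ")")
    }
    root <- parentless
  } else {
    if (!root %in% ids) stop("root class '", root, "' not in ontology")
    if (!identical(sort(parentless), sort(root))) {
      stop("class(es) not reaching root '", root, "': ",
           paste(setdiff(parentless, root), collapse = ", "))
    }
  }

  structure(list(classes = classes, root = root),
            class = "phenotype_ontology")
}

# Kahn peeling on the child->parent graph; returns ids stuck in cycles
# (empty for a DAG).
.find_cycle_members <- function(classes) {
  ids <- names(classes)
  outdeg <- vapply(classes, function(x) length(x$parents), integer(1))
  children <- list()  # parent -> children
  for (x in classes) {
    for (p in x$parents) children[[p]] <- c(children[[p]], x$id)
  }
  queue <- ids[outdeg == 0]
  removed <- 0L
  while (length(queue) > 0) {
    v <- queue[[1]]
    queue <- queue[-1]
    removed <- removed + 1L
    for (ch in children[[v]]) {
      outdeg[[ch]] <- outdeg[[ch]] - 1L
      if (outdeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (removed == length(ids)) character() else ids[outdeg > 0]
}

#' @export
print.phenotype_ontology <- function(x, ...) {
  cat("phenotype_ontology:", length(x$classes), "classes, root =",
      x$root, "\n")
  nsev <- sum(!vapply(x$classes, function(cl) is.na(cl$severity), logical(1)))
  cat("  severity-qualified subclasses:", nsev, "\n")
  invisible(x)
}

#' Ontology class identifiers
#' @param ont a `phenotype_ontology`.
#' @return character vector of class ids.
#' @export
class_ids <- function(ont) names(ont$classes)

.check_known <- function(ont, ids, what = "class") {
  missing <- setdiff(ids, names(ont$classes))
  if (length(missing) > 0) {
    stop("unknown ", what, " id(s): ", paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

#' Ancestor closure of a class
#'
#' Transitive closure over is_a parents, excluding the class itself.  This is
#' the subsumption relation that lets the engine conclude, e.g., that a
#' patient with abasia also has gait ataxia.
#'
#' @param ont a `phenotype_ontology`.
#' @param id class identifier.
#' @return character vector (set) of ancestor ids.
#' @export
ancestors <- function(ont, id) {
  .check_known(ont, id)
  seen <- character()
  frontier <- ont$classes[[id]]$parents
  while (length(frontier) > 0) {
    new <- setdiff(frontier, seen)
    seen <- c(seen, new)
    frontier <- unique(unlist(lapply(new, function(p) ont$classes[[p]]$parents)))
  }
  sort(seen)
}

#' Extract a seed-based ontology module
#'
#' Returns the self-contained sub-ontology induced by a set of seed classes:
#' the seeds together with all their ancestors, with is_a edges restricted to
#' the retained classes.  The result is upward-closed, so it is itself a
#' valid rooted ontology (a "slim" usable on its own).
#'
#' @param ont a `phenotype_ontology`.
#' @param seeds character vector of seed class ids.
#' @return a `phenotype_ontology` containing `seeds` and their ancestors.
#' @export
extract_module <- function(ont, seeds) {
  if (length(seeds) == 0) stop("at least one seed class is required")
  .check_known(ont, seeds, "seed")
  keep <- unique(c(seeds, unlist(lapply(seeds, ancestors, ont = ont))))
  classes <- lapply(ont$classes[keep], function(cl) {
    cl$parents <- intersect(cl$parents, keep)
    cl
  })
  root <- if (ont$root %in% keep) ont$root else NULL
  phenotype_ontology(unname(classes), root = root)
}

#' Generate severity subclasses of a base class
#'
#' For each requested level adds a subclass of `base` carrying that severity
#' qualifier, e.g. `moderate_dysarthria` as a subclass of `dysarthria` with
#' severity `moderate`.  Generated ids follow the deterministic scheme
#' `<level>_<base id>`.
#'
#' @param ont a `phenotype_ontology`.
#' @param base identifier of the class to specialize.
#' @param levels character vector of levels from [SEVERITY_LEVELS].
#' @return a new `phenotype_ontology` including the generated subclasses.
#' @export
add_severity_subclasses <- function(ont, base, levels = SEVERITY_LEVELS) {
  .check_known(ont, base)
  bad <- setdiff(levels, SEVERITY_LEVELS)
  if (length(bad) > 0) {
    stop("invalid severity level(s): ", paste(bad, collapse = ", "))
  }
  if (length(levels) == 0) return(ont)
  new_ids <- paste0(levels, "_", base)
  clash <- intersect(new_ids, names(ont$classes))
  if (length(clash) > 0) {
    stop("severity subclass id(s) already exist: ",
         paste(clash, collapse = ", "))
  }
  base_label <- ont$classes[[base]]$label
  additions <- Map(function(id, lev) {
    onto_class(id, label = paste(lev, base_label), parents = base,
               severity = lev)
  }, new_ids, levels)
  phenotype_ontology(c(unname(ont$classes), unname(additions)),
                     root = ont$root)
}

#' Classify an individual by named-class subsumption
#'
#' Given the classes asserted for one patient, returns the full inferred set:
#' the asserted classes plus every ancestor.  This is the closure a DL
#' reasoner would assign under asserted named-class subsumption, and is the
#' inference step behind the clinical synopsis.
#'
#' @param ont a `phenotype_ontology`.
#' @param asserted character vector of asserted class ids (may be empty).
#' @return sorted character vector of inferred class ids.
#' @export
classify_individual <- function(ont, asserted) {
  if (length(asserted) == 0) return(character())
  .check_known(ont, asserted)
  sort(unique(c(asserted, unlist(lapply(asserted, ancestors, ont = ont)))))
}

#' Subclasses (direct and indirect) of a class
#'
#' @param ont a `phenotype_ontology`.
#' @param id class identifier.
#' @return character vector of all descendant ids (excluding `id`).
#' @export
descendants <- function(ont, id) {
  .check_known(ont, id)
  ids <- names(ont$classes)
  sort(ids[vapply(ids, function(x) id %in% ancestors(ont, x), logical(1))])
}
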