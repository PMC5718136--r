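# SARA content model: item definitions, cluster bindings, and validated
# patient observations (the Observation-archetype analogue).

SARA_ITEM_IDS <- c("gait", "stance", "sitting", "speech",
                   "finger_chase", "nose_finger", "alternating_hand",
                   "heel_shin")
SARA_BILATERAL_ITEMS <- SARA_ITEM_IDS[5:8]
SARA_CLUSTERS <- c("gait_and_balance", "speech_disturbance",
                   "limb_coordination")

# canonical CSV / score-map keys: axial items bare, lateral items with _r/_l
sara_score_keys <- function() {
  c(SARA_ITEM_IDS[1:4],
    as.vector(rbind(paste0(SARA_BILATERAL_ITEMS, "_r"),
                    paste0(SARA_BILATERAL_ITEMS, "_l"))))
}

#' Load a SARA scale definition from a YAML config
#'
#' The config declares the eight items with their integer score ranges,
#' bilateral flags, cluster membership and phenotype-ontology bindings, plus
#' the cluster-to-ontology bindings.  Validation enforces the SARA shape:
#' exactly the eight canonical items, bilateral flags on exactly the four
#' limb items, ranges starting at 0, and a maximum total of 40 (bilateral
#' items counted once, as the maximum of the side mean).
#'
#' @param path path to a YAML config; defaults to the packaged canonical
#'   SARA definition.
#' @param ont optional [phenotype_ontology()]; when supplied, every item and
#'   cluster binding must resolve to a class in it.
#' @return an object of class `scale_definition`.
#' @export
load_scale_definition <- function(path = NULL, ont = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "sara_scale.yaml",
                        package = "sarainterp", mustWork = TRUE)
  }
  if (!file.exists(path)) stop("scale config not found: ", path)
  cfg <- yaml::read_yaml(path)
  errs <- character()

  items <- cfg$items
  if (is.null(items) || length(items) != 8) {
    stop("scale config must define exactly 8 items (found ",
         length(items), ")")
  }
  ids <- vapply(items, function(x) as.character(x$id %||% NA), character(1))
  if (!identical(ids, SARA_ITEM_IDS)) {
    errs <- c(errs, paste0("items must be exactly (in order): ",
                           paste(SARA_ITEM_IDS, collapse = ", ")))
  }
  for (it in items) {
    id <- as.character(it$id)
    mn <- it$min; mx <- it$max
    if (is.null(mn) || is.null(mx) || !is.numeric(mn) || !is.numeric(mx) ||
        mn != 0 || mx <= mn || mx != as.integer(mx)) {
      errs <- c(errs, paste0("item '", id,
                             "': range must be integers 0 = min < max"))
    }
    if (!is.logical(it$bilateral %||% NA)) {
      errs <- c(errs, paste0("item '", id, "': bilateral flag missing"))
    } else if (!identical(it$bilateral, id %in% SARA_BILATERAL_ITEMS)) {
      errs <- c(errs, paste0("item '", id, "': bilateral must be ",
                             id %in% SARA_BILATERAL_ITEMS))
    }
    if (is.null(it$binding) || !nzchar(it$binding)) {
      errs <- c(errs, paste0("item '", id, "': missing ontology binding"))
    }
    if (!(it$cluster %||% "") %in% SARA_CLUSTERS) {
      errs <- c(errs, paste0("item '", id, "': cluster must be one of ",
                             paste(SARA_CLUSTERS, collapse = ", ")))
    }
  }
  if (length(errs) == 0) {
    max_total <- sum(vapply(items, function(x) as.numeric(x$max), numeric(1)))
    if (max_total != 40) {
      errs <- c(errs, paste0("sum of item maxima must be 40, got ", max_total))
    }
  }
  clusters <- cfg$clusters
  if (!setequal(names(clusters), SARA_CLUSTERS)) {
    errs <- c(errs, "clusters must bind exactly gait_and_balance, speech_disturbance, limb_coordination")
  }
  if (length(errs) > 0) {
    stop("invalid scale definition:\n  - ", paste(errs, collapse = "\n  - "))
  }

  defs <- lapply(items, function(it) {
    list(item_id = as.character(it$id),
         label = as.character(it$label %||% it$id),
         min_score = as.integer(it$min), max_score = as.integer(it$max),
         bilateral = isTRUE(it$bilateral),
         binding = as.character(it$binding),
         cluster = as.character(it$cluster))
  })
  names(defs) <- ids
  scale <- structure(
    list(name = cfg$name %||% "SARA", version = cfg$version %||% "1.0",
         items = defs,
         cluster_bindings = unlist(clusters)[SARA_CLUSTERS]),
    class = "scale_definition"
  )
  if (!is.null(ont)) resolve_bindings(scale, ont)
  scale
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Check that all scale bindings resolve in an ontology
#' @param scale a `scale_definition`.
#' @param ont a [phenotype_ontology()].
#' @return `TRUE` invisibly; error listing unresolved bindings otherwise.
#' @export
resolve_bindings <- function(scale, ont) {
  bindings <- c(vapply(scale$items, function(x) x$binding, character(1)),
                scale$cluster_bindings)
  missing <- setdiff(bindings, class_ids(ont))
  if (length(missing) > 0) {
    stop("unresolved ontology binding(s): ", paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

#' @export
print.scale_definition <- function(x, ...) {
  cat(x$name, "scale definition (", length(x$items), "items )\n")
  for (it in x$items) {
    cat(sprintf("  %-17s [%d, %d]%s -> %s (%s)\n", it$item_id, it$min_score,
                it$max_score, if (it$bilateral) " R/L" else "    ",
                it$binding, it$cluster))
  }
  invisible(x)
}

#' Validate one patient's raw SARA scores
#'
#' Checks the full 12-entry score map (four axial items, four bilateral
#' items with `_r`/`_l` keys) against the scale definition and reports every
#' violation at once: missing entries, unexpected keys, non-integer values,
#' out-of-range values.
#'
#' @param scale a `scale_definition`.
#' @param raw named list or vector of scores keyed as
#'   `gait, stance, sitting, speech, finger_chase_r, finger_chase_l, ...`.
#' @param patient_id record identifier.
#' @param date assessment date (ISO string).
#' @return an object of class `observation_record`.
#' @export
validate_observation <- function(scale, raw, patient_id = "anonymous",
                                 date = NA_character_) {
  keys <- sara_score_keys()
  raw <- as.list(raw)
  errs <- character()
  extra <- setdiff(names(raw), keys)
  if (length(extra) > 0) {
    errs <- c(errs, paste0("unexpected score key(s): ",
                           paste(extra, collapse = ", ")))
  }
  scores <- stats::setNames(numeric(length(keys)), keys)
  for (k in keys) {
    item <- sub("_(r|l)$", "", k)
    def <- scale$items[[item]]
    v <- raw[[k]]
    if (is.null(v) || (length(v) == 1 && is.na(v))) {
      errs <- c(errs, paste0("missing score: ", k))
      next
    }
    vn <- suppressWarnings(as.numeric(v))
    if (is.na(vn)) {
      errs <- c(errs, paste0("non-numeric score for ", k, ": '", v, "'"))
    } else if (vn != as.integer(vn)) {
      errs <- c(errs, paste0("non-integer score for ", k, ": ", vn))
    } else if (vn < def$min_score || vn > def$max_score) {
      errs <- c(errs, sprintf("out-of-range score for %s: %d (allowed [%d, %d])",
                              k, as.integer(vn), def$min_score, def$max_score))
    } else {
      scores[[k]] <- as.integer(vn)
    }
  }
  if (length(errs) > 0) {
    stop(errorCondition(
      paste0("invalid observation for '", patient_id, "':\n  - ",
             paste(errs, collapse = "\n  - ")),
      class = c("sara_validation_error", "error"),
      violations = errs
    ))
  }
  structure(list(patient_id = patient_id, date = date, scores = scores),
            class = "observation_record")
}

#' @export
print.observation_record <- function(x, ...) {
  cat("observation_record:", x$patient_id,
      if (!is.na(x$date)) paste0("(", x$date, ")") else "", "\n")
  print(x$scores)
  invisible(x)
}

#' Read patient observations from CSV
#'
#' Expected header:
#' `patient_id,date,gait,stance,sitting,speech,finger_chase_r,finger_chase_l,
#' nose_finger_r,nose_finger_l,alternating_hand_r,alternating_hand_l,
#' heel_shin_r,heel_shin_l`.  Every row is validated; all row-level problems
#' are collected and reported together with their line numbers.
#'
#' @param path CSV file path.
#' @param scale a `scale_definition`; defaults to the packaged SARA.
#' @return list of `observation_record`s (possibly empty).
#' @export
read_observations_csv <- function(path, scale = load_scale_definition()) {
  if (!file.exists(path)) stop("observation file not found: ", path)
  expected <- c("patient_id", "date", sara_score_keys())
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!identical(names(df), expected)) {
    stop("observation CSV header mismatch; expected: ",
         paste(expected, collapse = ","))
  }
  if (nrow(df) == 0) return(list())
  records <- list()
  errs <- character()
  for (i in seq_len(nrow(df))) {
    raw <- as.list(df[i, sara_score_keys()])
    rec <- tryCatch(
      validate_observation(scale, raw,
                           patient_id = df$patient_id[i], date = df$date[i]),
      sara_validation_error = function(e) e
    )
    if (inherits(rec, "error")) {
      errs <- c(errs, paste0("line ", i + 1L, ": ",
                             paste(rec$violations, collapse = "; ")))
    } else {
      records[[length(records) + 1L]] <- rec
    }
  }
  if (length(errs) > 0) {
    stop(errorCondition(
      paste0("invalid rows in ", path, ":\n  - ",
             paste(errs, collapse = "\n  - ")),
      class = c("sara_validation_error", "error"), violations = errs
    ))
  }
  records
}

#' Write observation records to CSV
#'
#' Inverse of [read_observations_csv()] (same column layout).
#'
#' @param records list of `observation_record`s.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_observations_csv <- function(records, path) {
  keys <- sara_score_keys()
  rows <- lapply(records, function(r) {
    cbind(data.frame(patient_id = r$patient_id, date = r$date,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(r$scores)))
  })
  df <- if (length(rows) > 0) do.call(rbind, rows) else
    stats::setNames(as.data.frame(matrix(nrow = 0, ncol = 2 + length(keys))),
                    c("patient_id", "date", keys))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
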