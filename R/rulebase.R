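# Declarative SARA rule base, fired in three deterministic stages:
#   calculation -> severity -> assessment
# mirroring the guideline-rule organization of the interpretation engine.
# Rules are data (serializable to YAML), not code, so a user-supplied
# cut-off table can replace the default binning verbatim.

# default per-item severity cut-offs.  All published anchors are honored:
# sitting 4 -> severe sitting instability; gait 8 -> abasia;
# speech 6 -> anarthria; stance 6 -> astasia.  Interior cut-offs are the
# package default and are fully overridable.
.default_cutoffs <- function(scale) {
  band <- function(item, lo, hi, class, severity) {
    data.frame(item = item, lo = lo, hi = hi, class = class,
               severity = severity, stringsAsFactors = FALSE)
  }
  bind <- function(item) scale$items[[item]]$binding
  rows <- rbind(
    band("gait", 0, 0, bind("gait"), "absent"),
    band("gait", 1, 2, bind("gait"), "mild"),
    band("gait", 3, 5, bind("gait"), "moderate"),
    band("gait", 6, 7, bind("gait"), "severe"),
    band("gait", 8, 8, "abasia", "profound"),
    band("stance", 0, 0, bind("stance"), "absent"),
    band("stance", 1, 2, bind("stance"), "mild"),
    band("stance", 3, 4, bind("stance"), "moderate"),
    band("stance", 5, 5, bind("stance"), "severe"),
    band("stance", 6, 6, "astasia", "profound"),
    band("sitting", 0, 0, bind("sitting"), "absent"),
    band("sitting", 1, 1, bind("sitting"), "mild"),
    band("sitting", 2, 3, bind("sitting"), "moderate"),
    band("sitting", 4, 4, bind("sitting"), "severe"),
    band("speech", 0, 0, bind("speech"), "absent"),
    band("speech", 1, 2, bind("speech"), "mild"),
    band("speech", 3, 4, bind("speech"), "moderate"),
    band("speech", 5, 5, bind("speech"), "severe"),
    band("speech", 6, 6, "anarthria", "profound")
  )
  for (item in SARA_BILATERAL_ITEMS) {
    rows <- rbind(rows,
                  band(item, 0, 0, bind(item), "absent"),
                  band(item, 1, 1, bind(item), "mild"),
                  band(item, 2, 3, bind(item), "moderate"),
                  band(item, 4, 4, bind(item), "severe"))
  }
  rows
}

# default cerebellar-syndrome banding over the total T.  The absent band
# T <= 1 is anchored to the published control mean of 0.4 +/- 1.1; the
# remaining bands are the package's heuristic default (the interpretation of
# the SARA total is not standardized) and are overridable.
.default_bands <- function() {
  data.frame(
    lower = c(-Inf, 1, 10, 20, 30),
    upper = c(1, 10, 20, 30, 40),
    category = c("absent", "mild", "moderate", "severe", "very severe"),
    stringsAsFactors = FALSE
  )
}

#' Syndrome assessment categories, in severity order
#' @export
SYNDROME_CATEGORIES <- c("absent", "mild", "moderate", "severe",
                         "very severe")

#' Build the SARA rule base
#'
#' Constructs the default declarative rule base: 5 calculation rules (one
#' side-mean per bilateral item plus the total), per-item severity cut-off
#' rules covering every reachable integer score, and syndrome-assessment
#' rules banding the total score.  Cut-offs and bands can be replaced by
#' drop-in tables; replacements are validated for disjoint, exhaustive
#' coverage at build time.
#'
#' @param scale a `scale_definition`.
#' @param cutoffs optional data frame with columns
#'   `item, lo, hi, class, severity` replacing the default severity binning.
#' @param bands optional data frame with columns `lower, upper, category`
#'   ((lower, upper] semantics) replacing the default syndrome banding.
#' @return an object of class `rule_base`.
#' @export
build_sara_rulebase <- function(scale, cutoffs = NULL, bands = NULL) {
  cutoffs <- cutoffs %||% .default_cutoffs(scale)
  bands <- bands %||% .default_bands()

  calc <- c(
    lapply(SARA_BILATERAL_ITEMS, function(item) {
      list(rule_id = paste0("calc.mean.", item), stage = "calculation",
           when = list(), then = list(type = "mean_of_sides", item = item,
                                      target = paste0(item, "_mean")))
    }),
    list(list(
      rule_id = "calc.total", stage = "calculation", when = list(),
      then = list(type = "sum",
                  elements = c(SARA_ITEM_IDS[1:4],
                               paste0(SARA_BILATERAL_ITEMS, "_mean")),
                  target = "total")
    ))
  )

  sev <- lapply(seq_len(nrow(cutoffs)), function(i) {
    r <- cutoffs[i, ]
    list(rule_id = sprintf("severity.%s.%d_%d", r$item, r$lo, r$hi),
         stage = "severity",
         when = list(list(element = r$item, comparator = "between",
                          value = c(r$lo, r$hi))),
         then = list(type = "assert_finding", class = r$class,
                     severity = r$severity))
  })

  assess <- lapply(seq_len(nrow(bands)), function(i) {
    b <- bands[i, ]
    list(rule_id = paste0("assessment.", gsub(" ", "_", b$category)),
         stage = "assessment",
         when = list(list(element = "total", comparator = "between_gt_le",
                          value = c(b$lower, b$upper))),
         then = list(type = "assess_syndrome", category = b$category))
  })

  rb <- structure(
    list(name = "sara-default", version = "1.0",
         rules = c(calc, sev, assess),
         cutoffs = cutoffs, bands = bands),
    class = "rule_base"
  )
  .validate_rulebase(rb, scale)
  rb
}

# build-time guarantee of the stage invariants: severity intervals disjoint
# and exhaustive over each item's integer score range; assessment bands
# disjoint and exhaustive over [0, 40] on the half-point grid.
.validate_rulebase <- function(rb, scale) {
  errs <- character()
  cutoffs <- rb$cutoffs
  unknown <- setdiff(unique(cutoffs$item), SARA_ITEM_IDS)
  if (length(unknown) > 0) {
    errs <- c(errs, paste0("cut-off rules for unknown item(s): ",
                           paste(unknown, collapse = ", ")))
  }
  bad_sev <- setdiff(unique(cutoffs$severity), c("absent", SEVERITY_LEVELS))
  if (length(bad_sev) > 0) {
    errs <- c(errs, paste0("invalid severity level(s) in cut-offs: ",
                           paste(bad_sev, collapse = ", ")))
  }
  for (item in SARA_ITEM_IDS) {
    def <- scale$items[[item]]
    rows <- cutoffs[cutoffs$item == item, , drop = FALSE]
    for (s in seq(def$min_score, def$max_score)) {
      hits <- sum(s >= rows$lo & s <= rows$hi)
      if (hits == 0) {
        errs <- c(errs, sprintf("item '%s': score %d matched by no severity rule",
                                item, s))
      } else if (hits > 1) {
        errs <- c(errs, sprintf("item '%s': score %d matched by %d overlapping severity rules",
                                item, s, hits))
      }
    }
  }
  grid <- seq(0, 40, by = 0.5)
  for (t in grid) {
    hits <- sum(t > rb$bands$lower & t <= rb$bands$upper)
    if (hits != 1) {
      errs <- c(errs, sprintf("total %.1f matched by %d assessment bands", t, hits))
    }
  }
  if (length(errs) > 0) {
    stop(errorCondition(
      paste0("invalid rule base configuration:\n  - ",
             paste(errs, collapse = "\n  - ")),
      class = c("sara_config_error", "error"), violations = errs
    ))
  }
  invisible(TRUE)
}

#' Rules of one stage
#' @param rb a `rule_base`.
#' @param stage one of `"calculation"`, `"severity"`, `"assessment"`.
#' @return list of rules.
#' @export
stage_rules <- function(rb, stage = c("calculation", "severity", "assessment")) {
  stage <- match.arg(stage)
  Filter(function(r) r$stage == stage, rb$rules)
}

#' @export
print.rule_base <- function(x, ...) {
  cat("rule_base '", x$name, "' v", x$version, "\n", sep = "")
  for (st in c("calculation", "severity", "assessment")) {
    cat(sprintf("  %-12s %3d rules\n", st, length(stage_rules(x, st))))
  }
  invisible(x)
}

#' Apply the calculation stage
#'
#' Fires the five calculation rules: the mean of both sides for each of the
#' four bilateral items, and the total
#' `T = s1 + s2 + s3 + s4 + m5 + m6 + m7 + m8`.
#'
#' @param rb a `rule_base`.
#' @param obs an `observation_record`.
#' @return an object of class `derived_scores` with elements `means` (named
#'   vector over the bilateral items) and `total`.
#' @export
apply_calculation_rules <- function(rb, obs) {
  env <- as.list(obs$scores)
  for (rule in stage_rules(rb, "calculation")) {
    th <- rule$then
    env[[th$target]] <- switch(
      th$type,
      mean_of_sides = (env[[paste0(th$item, "_r")]] +
                         env[[paste0(th$item, "_l")]]) / 2,
      sum = sum(unlist(env[th$elements])),
      stop("unknown calculation action: ", th$type)
    )
  }
  means <- stats::setNames(
    vapply(paste0(SARA_BILATERAL_ITEMS, "_mean"),
           function(k) env[[k]], numeric(1)),
    SARA_BILATERAL_ITEMS
  )
  structure(list(means = means, total = env$total),
            class = "derived_scores")
}

#' @export
print.derived_scores <- function(x, ...) {
  cat("derived_scores: total =", x$total, "\n")
  print(x$means)
  invisible(x)
}

#' Apply the severity cut-off stage
#'
#' Produces one finding per item -- per side for bilateral items, so that
#' lateralized findings feed the synopsis.  A score of 0 yields an explicit
#' `absent` finding; maximal anchor scores yield the terminal classes
#' (gait 8 -> abasia, stance 6 -> astasia, speech 6 -> anarthria).
#'
#' @param rb a `rule_base`.
#' @param obs an `observation_record`.
#' @param derived a `derived_scores` (kept in the signature because the
#'   severity stage fires after calculation in the staged pipeline).
#' @param scale a `scale_definition` supplying the cluster of each finding.
#' @return list of findings, each a list with fields `element`, `item`,
#'   `side`, `score`, `onto_class`, `severity`, `laterality`, `cluster`.
#' @export
apply_severity_rules <- function(rb, obs, derived = NULL,
                                 scale = load_scale_definition()) {
  rules <- stage_rules(rb, "severity")
  findings <- list()
  for (item in SARA_ITEM_IDS) {
    sides <- if (scale$items[[item]]$bilateral) c("right", "left") else NA
    for (side in sides) {
      key <- if (is.na(side)) item else
        paste0(item, "_", substr(side, 1, 1))
      score <- obs$scores[[key]]
      hits <- Filter(function(r) {
        c1 <- r$when[[1]]
        c1$element == item && score >= c1$value[1] && score <= c1$value[2]
      }, rules)
      if (length(hits) != 1) {
        stop(errorCondition(
          sprintf("score %d of item '%s' matched by %d severity rules",
                  score, item, length(hits)),
          class = c("sara_config_error", "error")
        ))
      }
      th <- hits[[1]]$then
      findings[[length(findings) + 1L]] <- list(
        element = key, item = item,
        side = if (is.na(side)) NA_character_ else side,
        score = score, onto_class = th$class, severity = th$severity,
        laterality = if (is.na(side)) NA_character_ else side,
        cluster = scale$items[[item]]$cluster,
        rule_id = hits[[1]]$rule_id
      )
    }
  }
  findings
}

#' Apply the syndrome-assessment stage
#'
#' Bands the total score into a categorical cerebellar-syndrome assessment.
#' The default banding is: T <= 1 absent, (1, 10] mild, (10, 20] moderate,
#' (20, 30] severe, > 30 very severe.
#'
#' @param rb a `rule_base`.
#' @param derived a `derived_scores`.
#' @return an object of class `syndrome_assessment` with `category`,
#'   `total`, `rule_id`.
#' @export
apply_assessment_rules <- function(rb, derived) {
  t <- derived$total
  hits <- Filter(function(r) {
    v <- r$when[[1]]$value
    t > v[1] && t <= v[2]
  }, stage_rules(rb, "assessment"))
  if (length(hits) != 1) {
    stop(errorCondition(
      sprintf("total %.1f matched by %d assessment rules", t, length(hits)),
      class = c("sara_config_error", "error")
    ))
  }
  structure(list(category = hits[[1]]$then$category, total = t,
                 rule_id = hits[[1]]$rule_id),
            class = "syndrome_assessment")
}

#' @export
print.syndrome_assessment <- function(x, ...) {
  cat("cerebellar syndrome:", x$category, sprintf("(total = %g)", x$total),
      "\n")
  invisible(x)
}

#' Run the full interpretation pipeline for one observation
#'
#' Fires the three rule stages in fixed order (calculation -> severity ->
#' assessment), infers the phenotype closure by subsumption over the
#' ontology, and composes the clinical synopsis and textual report.  The
#' pipeline is deterministic: identical inputs yield identical output.
#'
#' @param scale a `scale_definition`.
#' @param rb a `rule_base`.
#' @param ont a [phenotype_ontology()].
#' @param obs an `observation_record`.
#' @return an object of class `evaluation_record` with elements
#'   `patient_id`, `date`, `derived`, `findings`, `assessment`, `inferred`,
#'   `synopsis`, `report`, `fired_rules`.
#' @export
run_pipeline <- function(scale, rb, ont, obs) {
  resolve_bindings(scale, ont)
  derived <- apply_calculation_rules(rb, obs)
  findings <- apply_severity_rules(rb, obs, derived, scale)
  assessment <- apply_assessment_rules(rb, derived)
  inferred <- infer_phenotypes(ont, findings)
  ev <- structure(
    list(patient_id = obs$patient_id, date = obs$date, derived = derived,
         findings = findings, assessment = assessment, inferred = inferred,
         synopsis = NULL, report = NULL,
         fired_rules = c(vapply(stage_rules(rb, "calculation"),
                                function(r) r$rule_id, character(1)),
                         vapply(findings, function(f) f$rule_id, character(1)),
                         assessment$rule_id)),
    class = "evaluation_record"
  )
  ev$synopsis <- build_synopsis(ev, ont)
  ev$report <- render_report(ev)
  ev
}

#' Serialize a rule base to YAML
#' @param rb a `rule_base`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rulebase <- function(rb, path) {
  yaml::write_yaml(
    list(name = rb$name, version = rb$version,
         cutoffs = rb$cutoffs, bands = rb$bands),
    path
  )
  invisible(path)
}

#' Read a serialized rule base
#'
#' Rebuilds (and revalidates) the rule base from a YAML file written by
#' [write_rulebase()] or hand-authored with the same schema, e.g. a drop-in
#' severity cut-off table.
#'
#' @param path YAML file path.
#' @param scale a `scale_definition`.
#' @return a `rule_base`.
#' @export
read_rulebase <- function(path, scale = load_scale_definition()) {
  if (!file.exists(path)) stop("rule base file not found: ", path)
  cfg <- yaml::read_yaml(path)
  to_df <- function(x) {
    if (is.data.frame(x)) return(x)
    if (all(vapply(x, is.list, logical(1)))) {
      do.call(rbind, lapply(x, as.data.frame))      # list of row records
    } else {
      as.data.frame(x, stringsAsFactors = FALSE)    # named column lists
    }
  }
  bands <- to_df(cfg$bands)
  bands$lower <- as.numeric(bands$lower)  # YAML may round-trip -Inf as string
  rb <- build_sara_rulebase(scale, cutoffs = to_df(cfg$cutoffs),
                            bands = bands)
  rb$name <- cfg$name %||% rb$name
  rb$version <- as.character(cfg$version %||% rb$version)
  rb
}
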