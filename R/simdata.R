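# Fixture and synthetic-data generators: the three worked-example patients,
# archetypal random patient profiles, and noisy-rater simulation for the
# agreement harness.  All randomness is seeded locally; the caller's RNG
# state is never disturbed.

PROFILE_ARCHETYPES <- c("none", "midline_dominant", "appendicular_symmetric",
                        "appendicular_asymmetric", "mixed")

# run code under a local seed, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' The three worked-example patients
#'
#' Three hypothetical patients sharing the same total SARA score of 20 but
#' with very different functional profiles: patient 1 is midline-dominant
#' (high gait/stance/sitting), patient 2 has symmetric appendicular
#' involvement with mildly affected speech, patient 3 combines anarthric
#' speech with a strongly asymmetrical (left-loaded) appendicular syndrome.
#'
#' @param scale a `scale_definition` used to validate the records.
#' @return list of three `observation_record`s.
#' @export
table1_patients <- function(scale = load_scale_definition()) {
  rows <- list(
    patient_1 = c(gait = 6, stance = 6, sitting = 3, speech = 1,
                  finger_chase_r = 0, finger_chase_l = 0,
                  nose_finger_r = 1, nose_finger_l = 1,
                  alternating_hand_r = 1, alternating_hand_l = 1,
                  heel_shin_r = 2, heel_shin_l = 2),
    patient_2 = c(gait = 2, stance = 2, sitting = 1, speech = 3,
                  finger_chase_r = 3, finger_chase_l = 4,
                  nose_finger_r = 3, nose_finger_l = 4,
                  alternating_hand_r = 3, alternating_hand_l = 3,
                  heel_shin_r = 2, heel_shin_l = 2),
    patient_3 = c(gait = 2, stance = 2, sitting = 1, speech = 6,
                  finger_chase_r = 1, finger_chase_l = 4,
                  nose_finger_r = 1, nose_finger_l = 4,
                  alternating_hand_r = 1, alternating_hand_l = 4,
                  heel_shin_r = 0, heel_shin_l = 3)
  )
  Map(function(raw, id) {
    validate_observation(scale, raw, patient_id = id, date = NA_character_)
  }, rows, names(rows))
}

# syndrome band -> (lower, upper] range of the total
.band_range <- function(band) {
  ranges <- list(absent = c(0, 1), mild = c(1, 10), moderate = c(10, 20),
                 severe = c(20, 30), "very severe" = c(30, 40))
  if (!band %in% names(ranges)) {
    stop("unknown severity band '", band, "'; expected one of: ",
         paste(names(ranges), collapse = ", "))
  }
  ranges[[band]]
}

# per-slot score caps for each archetype; lateral slots keyed item_r/item_l
.archetype_caps <- function(scale, archetype, loaded_side) {
  keys <- sara_score_keys()
  caps <- stats::setNames(vapply(keys, function(k) {
    scale$items[[sub("_(r|l)$", "", k)]]$max_score
  }, numeric(1)), keys)
  axial3 <- c("gait", "stance", "sitting")
  lateral <- grep("_(r|l)$", keys, value = TRUE)
  if (archetype == "midline_dominant") {
    caps["speech"] <- pmin(caps["speech"], 2)
    caps[lateral] <- pmin(caps[lateral], 1)
  } else if (archetype %in% c("appendicular_symmetric",
                              "appendicular_asymmetric")) {
    caps[axial3] <- pmin(caps[axial3], 2)
    caps["speech"] <- pmin(caps["speech"], 2)
    if (archetype == "appendicular_asymmetric") {
      off <- grep(paste0("_", if (loaded_side == "r") "l" else "r", "$"),
                  lateral, value = TRUE)
      caps[off] <- pmin(caps[off], 1)
    }
  }
  caps
}

#' Generate a synthetic patient profile
#'
#' Draws a random but reproducible observation whose total falls in the
#' requested syndrome band, with scores loaded according to the archetype:
#' `midline_dominant` loads gait/stance/sitting (speech and limb scores are
#' capped low, so its maximum total is 24); `appendicular_symmetric` loads
#' the four limb items evenly on both sides; `appendicular_asymmetric`
#' loads one side (chosen by the seed) and guarantees that the loaded side's
#' summed limb scores strictly exceed the other side's; `mixed` is
#' unconstrained; `none` is the all-zero record (absent band only).
#'
#' @param scale a `scale_definition`.
#' @param archetype one of
#'   `none, midline_dominant, appendicular_symmetric,
#'   appendicular_asymmetric, mixed`.
#' @param band target syndrome band for the total
#'   (`absent, mild, moderate, severe, very severe`).
#' @param seed integer seed; identical seeds yield identical records.
#' @return an `observation_record` passing [validate_observation()].
#' @export
generate_profile <- function(scale, archetype = "mixed", band = "moderate",
                             seed = 1L) {
  archetype <- match.arg(archetype, PROFILE_ARCHETYPES)
  range <- .band_range(band)
  pid <- sprintf("sim_%s_%s_%d", archetype, gsub(" ", "", band), seed)

  if (archetype == "none") {
    if (band != "absent") {
      stop("archetype 'none' can only realize the absent band")
    }
    return(validate_observation(
      scale, stats::setNames(rep(0, 12), sara_score_keys()),
      patient_id = pid))
  }

  .with_seed(seed, {
    loaded_side <- sample(c("r", "l"), 1)
    caps <- .archetype_caps(scale, archetype, loaded_side)
    lateral <- grep("_(r|l)$", names(caps), value = TRUE)
    axial <- setdiff(names(caps), lateral)
    t_contrib <- stats::setNames(ifelse(names(caps) %in% lateral, 0.5, 1),
                                 names(caps))
    t_max <- sum(caps * t_contrib)

    lo <- range[1] + 0.5  # bands are (lower, upper]; totals move in halves
    hi <- min(range[2], t_max)
    targets <- if (hi < lo) numeric() else seq(lo, hi, by = 0.5)
    if (length(targets) == 0) {
      stop("archetype '", archetype, "' cannot reach the '", band,
           "' band (maximum total ", t_max, ")")
    }
    target <- if (length(targets) == 1) targets else sample(targets, 1)

    scores <- stats::setNames(rep(0, length(caps)), names(caps))
    total <- 0
    limb_sum <- function(side) {
      sum(scores[grep(paste0("_", side, "$"), lateral, value = TRUE)])
    }
    first_step <- TRUE
    while (total < target) {
      remaining <- target - total
      cand <- names(caps)[scores < caps]
      if (archetype == "appendicular_asymmetric") {
        off <- if (loaded_side == "r") "l" else "r"
        off_keys <- grep(paste0("_", off, "$"), lateral, value = TRUE)
        if (limb_sum(loaded_side) < limb_sum(off) + 2) {
          cand <- setdiff(cand, off_keys)
        }
        if (first_step) {
          cand <- intersect(cand, grep(paste0("_", loaded_side, "$"),
                                       lateral, value = TRUE))
        }
      }
      if (archetype == "appendicular_symmetric") {
        # keep the two sides within one point of each other
        cand <- Filter(function(k) {
          if (!k %in% lateral) return(TRUE)
          side <- sub("^.*_", "", k)
          other <- if (side == "r") "l" else "r"
          limb_sum(side) + 1 - limb_sum(other) <= 1
        }, cand)
        if (first_step) cand <- intersect(cand, lateral)
      }
      # every increment must leave the residual target reachable
      cand <- Filter(function(k) {
        r2 <- remaining - t_contrib[[k]]
        if (r2 < 0) return(FALSE)
        left <- caps - scores
        left[[k]] <- left[[k]] - 1
        lat_cap <- sum(left[lateral]) * 0.5
        ax_cap <- sum(left[axial])
        r2 <= lat_cap + ax_cap && (r2 %% 1 == 0 || lat_cap >= 0.5)
      }, cand)
      if (length(cand) == 0) {
        stop("archetype '", archetype,
             "' cannot realize total ", target, " in band '", band, "'")
      }
      pick <- if (length(cand) == 1) cand else sample(cand, 1)
      scores[[pick]] <- scores[[pick]] + 1
      total <- total + t_contrib[[pick]]
      first_step <- FALSE
    }
    validate_observation(scale, scores, patient_id = pid)
  })
}

#' Simulate two noisy raters over a ground-truth ordinal sequence
#'
#' Each rater independently reports the true label with probability
#' `agreement_prob`; otherwise the report is drawn uniformly from the
#' categories within `drift` ordinal steps of the truth (excluding the
#' truth, clamped to the scale ends).  With `drift >= k - 1` the
#' disagreement target is uniform over all other categories, so
#' `agreement_prob = 1/k` yields chance-level agreement.
#'
#' @param truth character vector of true labels.
#' @param categories ordered category labels; `truth` must come from it.
#' @param agreement_prob per-rating probability of reporting the truth.
#' @param drift maximum ordinal displacement of a disagreeing report
#'   (integer >= 1).
#' @param seed integer seed.
#' @return list with character vectors `rater_a` and `rater_b`.
#' @export
simulate_raters <- function(truth, categories, agreement_prob = 0.9,
                            drift = 1L, seed = 1L) {
  if (length(truth) == 0) stop("truth must be non-empty")
  if (agreement_prob < 0 || agreement_prob > 1) {
    stop("agreement_prob must be in [0, 1]")
  }
  if (drift < 1) stop("drift must be >= 1")
  unknown <- setdiff(unique(truth), categories)
  if (length(unknown) > 0) {
    stop("truth label(s) not in categories: ", paste(unknown, collapse = ", "))
  }
  k <- length(categories)
  ti <- match(truth, categories)
  .with_seed(seed, {
    rate_once <- function() {
      vapply(ti, function(i) {
        if (stats::runif(1) < agreement_prob) return(categories[i])
        neigh <- setdiff(max(1, i - drift):min(k, i + drift), i)
        categories[if (length(neigh) == 1) neigh else sample(neigh, 1)]
      }, character(1))
    }
    list(rater_a = rate_once(), rater_b = rate_once())
  })
}

#' Generate a random toy ontology DAG
#'
#' A rooted random DAG for property testing of the subsumption machinery:
#' node `i`'s parents are drawn from nodes `1..i-1` (node 1 is the root), so
#' the graph is acyclic by construction.
#'
#' @param n number of classes (>= 1).
#' @param p_extra probability of each additional (multi-inheritance) parent.
#' @param seed integer seed.
#' @return a [phenotype_ontology()] with classes `t1..tn`, root `t1`.
#' @export
random_ontology <- function(n, p_extra = 0.2, seed = 1L) {
  stopifnot(n >= 1)
  .with_seed(seed, {
    classes <- list(onto_class("t1"))
    for (i in seq_len(n - 1) + 1) {
      pool <- paste0("t", seq_len(i - 1))
      parents <- pool[[if (i == 2) 1 else sample(i - 1, 1)]]
      extra <- pool[stats::runif(i - 1) < p_extra]
      classes[[i]] <- onto_class(paste0("t", i),
                                 parents = unique(c(parents, extra)))
    }
    phenotype_ontology(classes, root = "t1")
  })
}
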