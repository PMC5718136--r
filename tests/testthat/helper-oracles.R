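# Independent oracles for property tests.  These deliberately re-derive the
# quantities by brute force, staying independent of the package internals
# they are used to check.

# is_a edge list (child -> parent) of an ontology
edge_list <- function(ont) {
  do.call(rbind, lapply(ont$classes, function(cl) {
    if (length(cl$parents) == 0) return(NULL)
    data.frame(child = cl$id, parent = cl$parents, stringsAsFactors = FALSE)
  }))
}

# brute-force reachability over the reversed edge list: iterate a frontier
# of direct-parent lookups until fixpoint
bf_ancestors <- function(ont, id) {
  edges <- edge_list(ont)
  reached <- character()
  frontier <- id
  repeat {
    nxt <- unique(edges$parent[edges$child %in% frontier])
    nxt <- setdiff(nxt, reached)
    if (length(nxt) == 0) break
    reached <- c(reached, nxt)
    frontier <- nxt
  }
  sort(setdiff(reached, id))
}

# brute-force weighted kappa: explicit loops over all cell pairs
bf_weighted_kappa <- function(counts, scheme = "linear") {
  k <- nrow(counts)
  n <- sum(counts)
  rows <- rowSums(counts)
  cols <- colSums(counts)
  num <- 0
  den <- 0
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      w <- if (scheme == "linear") abs(i - j) / (k - 1) else
        (i - j)^2 / (k - 1)^2
      num <- num + w * counts[i, j]
      den <- den + w * rows[i] * cols[j] / n
    }
  }
  if (den == 0) return(NA_real_)
  1 - num / den
}

# random k x k contingency table with all-positive marginals
random_counts <- function(k, n = 200, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::rpois(k * k, lambda = n / k^2) + 1L, k, k)
  m
}

# brute-force observation validity: enumerate all 12 constraints directly
bf_observation_valid <- function(scale, raw) {
  keys <- c("gait", "stance", "sitting", "speech",
            paste0(rep(c("finger_chase", "nose_finger", "alternating_hand",
                         "heel_shin"), each = 2), c("_r", "_l")))
  if (!setequal(names(raw), keys)) return(FALSE)
  for (k in keys) {
    item <- sub("_(r|l)$", "", k)
    v <- suppressWarnings(as.numeric(raw[[k]]))
    if (length(v) != 1 || is.na(v) || v != round(v)) return(FALSE)
    if (v < scale$items[[item]]$min_score ||
        v > scale$items[[item]]$max_score) return(FALSE)
  }
  TRUE
}

# shared fixtures
sara_ont <- sara_ontology()
sara_scale <- load_scale_definition(ont = sara_ont)
sara_rb <- build_sara_rulebase(sara_scale)

# toy ontology used across ontology tests: root <- {A <- {A1, A2}, B <- B1}
toy_ontology <- function() {
  phenotype_ontology(list(
    onto_class("root"),
    onto_class("A", parents = "root"),
    onto_class("A1", parents = "A"),
    onto_class("A2", parents = "A"),
    onto_class("B", parents = "root"),
    onto_class("B1", parents = "B")
  ))
}

# observation with every item at a constant score (clipped to item maxima)
flat_observation <- function(scale, value) {
  keys <- c("gait", "stance", "sitting", "speech",
            paste0(rep(c("finger_chase", "nose_finger", "alternating_hand",
                         "heel_shin"), each = 2), c("_r", "_l")))
  raw <- vapply(keys, function(k) {
    item <- sub("_(r|l)$", "", k)
    min(value, scale$items[[item]]$max_score)
  }, numeric(1))
  validate_observation(scale, raw, patient_id = paste0("flat_", value))
}
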