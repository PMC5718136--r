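test_that("the default rule base has five calculation rules", {
  expect_length(stage_rules(sara_rb, "calculation"), 5)
  targets <- vapply(stage_rules(sara_rb, "calculation"),
                    function(r) r$then$target, character(1))
  expect_setequal(targets, c("finger_chase_mean", "nose_finger_mean",
                             "alternating_hand_mean", "heel_shin_mean",
                             "total"))
})

test_that("every integer score of every item matches exactly one severity rule", {
  rules <- stage_rules(sara_rb, "severity")
  for (item in names(sara_scale$items)) {
    for (s in 0:sara_scale$items[[item]]$max_score) {
      hits <- Filter(function(r) {
        c1 <- r$when[[1]]
        c1$element == item && s >= c1$value[1] && s <= c1$value[2]
      }, rules)
      expect_length(hits, 1)
    }
  }
})

test_that("calculation rules reproduce the worked-example derived scores", {
  pats <- table1_patients(sara_scale)
  d <- lapply(pats, apply_calculation_rules, rb = sara_rb)
  expect_identical(vapply(d, function(x) x$total, numeric(1)),
                   c(patient_1 = 20, patient_2 = 20, patient_3 = 20))
  expect_identical(unname(d$patient_1$means),
                   c(0, 1, 1, 2))
  expect_identical(unname(d$patient_2$means),
                   c(3.5, 3.5, 3, 2))
  expect_identical(unname(d$patient_3$means),
                   c(2.5, 2.5, 2.5, 1.5))
  zero <- apply_calculation_rules(sara_rb, flat_observation(sara_scale, 0))
  expect_identical(zero$total, 0)
  expect_true(all(zero$means == 0))
})

test_that("severity anchors map to the published classes", {
  find_for <- function(raw_overrides) {
    raw <- stats::setNames(rep(0, 12),
                           names(flat_observation(sara_scale, 0)$scores))
    raw[names(raw_overrides)] <- raw_overrides
    obs <- validate_observation(sara_scale, raw)
    apply_severity_rules(sara_rb, obs, scale = sara_scale)
  }
  by_el <- function(fs, el) Filter(function(f) f$element == el, fs)[[1]]

  f <- by_el(find_for(c(sitting = 4)), "sitting")
  expect_identical(f$onto_class, "sitting_instability")
  expect_identical(f$severity, "severe")

  f <- by_el(find_for(c(gait = 8)), "gait")
  expect_identical(f$onto_class, "abasia")

  f <- by_el(find_for(c(speech = 6)), "speech")
  expect_identical(f$onto_class, "anarthria")

  f <- by_el(find_for(c(stance = 6)), "stance")
  expect_identical(f$onto_class, "astasia")

  f <- by_el(find_for(c(gait = 3)), "gait")
  expect_identical(f$onto_class, "gait_ataxia")
  expect_identical(f$severity, "moderate")

  # score 0 yields an explicit absent finding on the bound class
  f <- by_el(find_for(c(gait = 0)), "gait")
  expect_identical(f$severity, "absent")
  expect_identical(f$onto_class, "gait_ataxia")

  # bilateral items yield lateralized findings per side
  fs <- find_for(c(finger_chase_l = 4))
  expect_identical(by_el(fs, "finger_chase_l")$severity, "severe")
  expect_identical(by_el(fs, "finger_chase_l")$laterality, "left")
  expect_identical(by_el(fs, "finger_chase_r")$severity, "absent")
})

test_that("severity is monotone in the score for every item", {
  rank_of <- function(item, s) {
    rules <- stage_rules(sara_rb, "severity")
    hit <- Filter(function(r) {
      c1 <- r$when[[1]]
      c1$element == item && s >= c1$value[1] && s <= c1$value[2]
    }, rules)[[1]]
    severity_rank(hit$then$severity)
  }
  for (item in names(sara_scale$items)) {
    scores <- 0:sara_scale$items[[item]]$max_score
    ranks <- vapply(scores, rank_of, item = item, numeric(1))
    expect_true(all(diff(ranks) >= 0))
  }
})

test_that("the total is monotone in every raw score", {
  set.seed(3)
  keys <- names(flat_observation(sara_scale, 0)$scores)
  for (i in 1:25) {
    raw <- vapply(keys, function(k) {
      item <- sub("_(r|l)$", "", k)
      sample(0:(sara_scale$items[[item]]$max_score - 1), 1)
    }, numeric(1))
    base_total <- apply_calculation_rules(
      sara_rb, validate_observation(sara_scale, raw))$total
    k <- sample(keys, 1)
    raw[[k]] <- raw[[k]] + 1
    new_total <- apply_calculation_rules(
      sara_rb, validate_observation(sara_scale, raw))$total
    expect_gt(new_total, base_total)
  }
})

test_that("syndrome banding is disjoint, exhaustive and anchored at T <= 1", {
  band_of <- function(t) {
    apply_assessment_rules(sara_rb, structure(list(total = t),
                                              class = "derived_scores"))$category
  }
  expect_identical(band_of(0), "absent")
  expect_identical(band_of(0.5), "absent")
  expect_identical(band_of(1), "absent")
  expect_identical(band_of(1.5), "mild")
  expect_identical(band_of(10), "mild")
  expect_identical(band_of(10.5), "moderate")
  expect_identical(band_of(20), "moderate")
  expect_identical(band_of(20.5), "severe")
  expect_identical(band_of(30), "severe")
  expect_identical(band_of(30.5), "very severe")
  expect_identical(band_of(40), "very severe")
  # exhaustive over the half grid
  cats <- vapply(seq(0, 40, 0.5), band_of, character(1))
  expect_setequal(unique(cats), SYNDROME_CATEGORIES)
})

test_that("cut-off overrides are validated for coverage and disjointness", {
  cuts <- sara_rb$cutoffs
  overlap <- cuts
  overlap$hi[overlap$item == "sitting" & overlap$lo == 1] <- 2  # 2 now double
  expect_error(build_sara_rulebase(sara_scale, cutoffs = overlap),
               "score 2 matched by 2 overlapping")
  expect_s3_class(
    tryCatch(build_sara_rulebase(sara_scale, cutoffs = overlap),
             error = function(e) e),
    "sara_config_error"
  )

  gap <- cuts[!(cuts$item == "speech" & cuts$lo == 3), ]
  expect_error(build_sara_rulebase(sara_scale, cutoffs = gap),
               "score 3 matched by no severity rule")

  bad_bands <- data.frame(lower = c(-Inf, 5), upper = c(5, 39),
                          category = c("absent", "severe"))
  expect_error(build_sara_rulebase(sara_scale, bands = bad_bands),
               "total 39.5 matched by 0")
})

test_that("a drop-in cut-off table is mirrored rule for rule", {
  # one rule per reachable integer score of every item
  per_score <- do.call(rbind, lapply(names(sara_scale$items), function(item) {
    def <- sara_scale$items[[item]]
    scores <- 0:def$max_score
    sev <- ifelse(scores == 0, "absent",
                  ifelse(scores <= 1, "mild",
                         ifelse(scores < def$max_score, "moderate", "severe")))
    data.frame(item = item, lo = scores, hi = scores, class = def$binding,
               severity = sev, stringsAsFactors = FALSE)
  }))
  rb <- build_sara_rulebase(sara_scale, cutoffs = per_score)
  expect_length(stage_rules(rb, "severity"), nrow(per_score))
  expect_identical(nrow(per_score), 48L)
})

test_that("rule bases round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_rulebase(sara_rb, path)
  rb2 <- read_rulebase(path, sara_scale)
  expect_identical(length(rb2$rules), length(sara_rb$rules))
  expect_identical(rb2$cutoffs$severity, sara_rb$cutoffs$severity)
  expect_identical(rb2$bands$category, sara_rb$bands$category)
  # behavior identical after round-trip
  obs <- table1_patients(sara_scale)[[1]]
  expect_identical(apply_calculation_rules(rb2, obs),
                   apply_calculation_rules(sara_rb, obs))
  expect_identical(apply_severity_rules(rb2, obs, scale = sara_scale),
                   apply_severity_rules(sara_rb, obs, scale = sara_scale))
})
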