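test_that("OBO loading parses a chain and computes its closure", {
  path <- withr::local_tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.4", "",
    "[Term]", "id: root", "name: root term", "",
    "[Term]", "id: A", "name: class A", "is_a: root ! root term", "",
    "[Term]", "id: B", "name: class B", "is_a: A", ""
  ), path)
  ont <- load_obo(path)
  expect_length(class_ids(ont), 3)
  expect_identical(ont$root, "root")
  expect_setequal(ancestors(ont, "B"), c("A", "root"))
  expect_identical(ancestors(ont, "root"), character())
})

test_that("cyclic and dangling hierarchies are rejected with offending ids", {
  path <- withr::local_tempfile(fileext = ".obo")
  writeLines(c(
    "[Term]", "id: root", "",
    "[Term]", "id: A", "is_a: B", "is_a: root", "",
    "[Term]", "id: B", "is_a: A", ""
  ), path)
  expect_error(load_obo(path), "cycle.*A, B")

  expect_error(
    phenotype_ontology(list(onto_class("r"),
                            onto_class("x", parents = "ghost"))),
    "dangling.*ghost"
  )
  expect_error(
    phenotype_ontology(list(onto_class("r"), onto_class("r"))),
    "duplicate"
  )
})

test_that("obsolete terms are excluded from the loaded graph", {
  path <- withr::local_tempfile(fileext = ".obo")
  writeLines(c(
    "[Term]", "id: root", "",
    "[Term]", "id: old", "is_a: root", "is_obsolete: true", "",
    "[Term]", "id: live", "is_a: root", ""
  ), path)
  expect_setequal(class_ids(load_obo(path)), c("root", "live"))
})

test_that("the packaged ontology has 109 subclasses of the root", {
  ont <- load_obo(sara_ontology_path())
  expect_identical(ont$root, "phenotypic_abnormality")
  expect_length(descendants(ont, "phenotypic_abnormality"), 109)
  # the packaged file is exactly the programmatic construction
  built <- sara_ontology()
  expect_setequal(class_ids(ont), class_ids(built))
  for (id in class_ids(built)) {
    expect_setequal(ont$classes[[id]]$parents, built$classes[[id]]$parents)
  }
})

test_that("acyclicity validation accepts random DAGs and rejects cycles", {
  for (seed in 1:5) {
    ont <- random_ontology(30, p_extra = 0.3, seed = seed)
    expect_s3_class(ont, "phenotype_ontology")
    # rewire one non-root class to point at a descendant -> cycle
    classes <- ont$classes
    victims <- setdiff(class_ids(ont), "t1")
    v <- victims[[1 + seed %% length(victims)]]
    desc <- descendants(ont, v)
    if (length(desc) == 0) next
    classes[[v]]$parents <- c(classes[[v]]$parents, desc[[1]])
    expect_error(phenotype_ontology(unname(classes), root = "t1"), "cycle")
  }
})

test_that("ancestors matches brute-force reachability on random DAGs", {
  for (seed in c(2, 7)) {
    ont <- random_ontology(200, p_extra = 0.05, seed = seed)
    for (id in class_ids(ont)) {
      expect_identical(ancestors(ont, id), bf_ancestors(ont, id))
    }
  }
  expect_error(ancestors(sara_ont, "no_such_class"), "unknown class")
})

test_that("abasia is subsumed by gait ataxia and truncal ataxia", {
  anc <- ancestors(sara_ont, "abasia")
  expect_true(all(c("gait_ataxia", "truncal_ataxia") %in% anc))
})

test_that("module extraction is the upward closure of the seeds", {
  toy <- toy_ontology()
  mod <- extract_module(toy, "A1")
  expect_setequal(class_ids(mod), c("root", "A", "A1"))

  expect_setequal(class_ids(extract_module(toy, "root")), "root")
  expect_error(extract_module(toy, c("A1", "nope")), "unknown seed.*nope")

  # seeding all leaves keeps exactly the classes on leaf-to-root paths
  ont <- random_ontology(60, p_extra = 0.15, seed = 11)
  leaves <- setdiff(class_ids(ont),
                    unique(unlist(lapply(ont$classes, `[[`, "parents"))))
  mod <- extract_module(ont, leaves)
  expected <- sort(unique(c(leaves,
                            unlist(lapply(leaves, bf_ancestors, ont = ont)))))
  expect_setequal(class_ids(mod), expected)
})

test_that("module extraction is idempotent and upward-closed", {
  for (seed in c(3, 9)) {
    ont <- random_ontology(80, p_extra = 0.2, seed = seed)
    set.seed(seed)
    seeds <- sample(class_ids(ont), 6)
    mod <- extract_module(ont, seeds)
    # upward-closed: every parent of a retained class is retained
    for (cl in mod$classes) {
      expect_true(all(cl$parents %in% class_ids(mod)))
    }
    mod2 <- extract_module(mod, seeds)
    expect_setequal(class_ids(mod2), class_ids(mod))
  }
})

test_that("severity subclasses are generated deterministically", {
  base <- phenotype_ontology(list(
    onto_class("root"), onto_class("dysarthria", parents = "root")
  ))
  ont <- add_severity_subclasses(base, "dysarthria", "moderate")
  cl <- ont$classes[["moderate_dysarthria"]]
  expect_identical(cl$parents, "dysarthria")
  expect_identical(cl$severity, "moderate")

  expect_identical(add_severity_subclasses(base, "dysarthria", character()),
                   base)
  expect_error(add_severity_subclasses(ont, "dysarthria", "moderate"),
               "already exist")
  expect_error(add_severity_subclasses(base, "dysarthria", "enormous"),
               "invalid severity")
})

test_that("severity subclasses inherit the ancestry of their base class", {
  base <- extract_module(sara_ont, "sitting_instability")
  ont <- add_severity_subclasses(base, "sitting_instability", SEVERITY_LEVELS)
  for (lev in SEVERITY_LEVELS) {
    id <- paste0(lev, "_sitting_instability")
    expect_true(all(c("sitting_instability",
                      bf_ancestors(base, "sitting_instability")) %in%
                      ancestors(ont, id)))
  }
})

test_that("individual classification is the union of ancestor closures", {
  inferred <- classify_individual(
    sara_ont, c("standing_instability", "sitting_instability"))
  expect_true(all(c("ataxic_postural_instability", "truncal_ataxia") %in%
                    inferred))
  expect_identical(classify_individual(sara_ont, character()), character())

  for (seed in c(5, 13)) {
    ont <- random_ontology(50, p_extra = 0.25, seed = seed)
    set.seed(seed)
    asserted <- sample(class_ids(ont), 5)
    expect_identical(
      classify_individual(ont, asserted),
      sort(unique(c(asserted, unlist(lapply(asserted, bf_ancestors,
                                            ont = ont)))))
    )
    # monotone in the asserted set
    small <- classify_individual(ont, asserted[1:2])
    big <- classify_individual(ont, asserted)
    expect_true(all(small %in% big))
  }
})

test_that("OBO round-trip preserves classes, edges and qualifiers", {
  for (ont in list(sara_ont, random_ontology(40, seed = 4))) {
    path <- withr::local_tempfile(fileext = ".obo")
    write_obo(ont, path)
    back <- load_obo(path)
    expect_setequal(class_ids(back), class_ids(ont))
    for (id in class_ids(ont)) {
      expect_setequal(back$classes[[id]]$parents, ont$classes[[id]]$parents)
      expect_identical(back$classes[[id]]$severity, ont$classes[[id]]$severity)
    }
  }
})

test_that("OWL import reads named subclass axioms and skips restrictions", {
  owl <- function(body) {
    paste0('<?xml version="1.0"?>\n',
           '<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"',
           ' xmlns:rdfs="http://www.w3.org/2000/01/rdf-schema#"',
           ' xmlns:owl="http://www.w3.org/2002/07/owl#">\n', body,
           '</rdf:RDF>\n')
  }
  minimal <- owl(paste0(
    '<owl:Class rdf:about="#root"/>\n',
    '<owl:Class rdf:about="#child">',
    '<rdfs:subClassOf rdf:resource="#root"/></owl:Class>\n'
  ))
  path <- withr::local_tempfile(fileext = ".owl")
  writeLines(minimal, path)
  ont <- import_owl_subclass_hierarchy(path)
  expect_setequal(class_ids(ont), c("root", "child"))
  expect_identical(ont$classes[["child"]]$parents, "root")

  with_restriction <- owl(paste0(
    '<owl:Class rdf:about="#root"/>\n',
    '<owl:Class rdf:about="#child">',
    '<rdfs:subClassOf rdf:resource="#root"/>',
    '<rdfs:subClassOf><owl:Restriction>',
    '<owl:onProperty rdf:resource="#p"/>',
    '</owl:Restriction></rdfs:subClassOf>',
    '</owl:Class>\n'
  ))
  path2 <- withr::local_tempfile(fileext = ".owl")
  writeLines(with_restriction, path2)
  expect_warning(ont2 <- import_owl_subclass_hierarchy(path2),
                 "skipped 1 non-named")
  expect_setequal(class_ids(ont2), class_ids(ont))
  expect_identical(ont2$classes[["child"]]$parents,
                   ont$classes[["child"]]$parents)
})

test_that("graph exports carry every class and is_a edge", {
  nl <- as_node_link(toy_ontology())
  expect_setequal(nl$nodes$id, c("root", "A", "A1", "A2", "B", "B1"))
  expect_identical(nrow(nl$links), 5L)
  path <- withr::local_tempfile(fileext = ".dot")
  write_dot(toy_ontology(), path)
  dot <- readLines(path)
  expect_true(any(grepl('"A1" -> "A"', dot, fixed = TRUE)))
})
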