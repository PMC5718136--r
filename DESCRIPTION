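Package: sarainterp
Title: Ontology-Aware Scoring and Interpretation of the SARA Ataxia Scale
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An interpretation engine for the Scale for the Assessment and
    Rating of Ataxia (SARA). Computes derived scores (bilateral means and the
    0-40 total), grades per-item severity through declarative cut-off rules,
    assesses the cerebellar syndrome from the total score, and infers a
    phenotype synopsis by subsumption reasoning over a scaled-down phenotype
    ontology shipped with the package. Includes an OBO flat-file subset
    reader/writer, an OWL/XML subclass-hierarchy importer, seed-based ontology
    module extraction, a weighted Cohen's kappa validation harness with
    Landis-Koch interpretation bands, synthetic patient and rater generators,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
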