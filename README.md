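# sarainterp

Ontology-aware scoring and interpretation of the **Scale for the Assessment
and Rating of Ataxia (SARA)**.

The SARA grades cerebellar ataxia through eight motor items — gait, stance,
sitting, speech disturbance, and four limb-coordination tests scored
bilaterally. The side means of the four bilateral items are added to the
first four scores, giving a total *T* ∈ [0, 40] (0 = no ataxia, 40 = most
severe ataxia). The total alone hides clinically crucial structure: two
patients with the same *T* can have completely different phenotypes (one can
barely stand; another speaks normally but has a severely ataxic left arm).

`sarainterp` turns the 12 raw scores into a qualitative clinical picture,
for neurologists and clinical-research engineers working with rating-scale
data:

1. **Calculation** — bilateral means *mᵢ = (R + L)/2* and the total
   *T = s₁ + s₂ + s₃ + s₄ + m₅ + m₆ + m₇ + m₈*, fired as declarative rules.
2. **Severity grading** — per-item cut-off rules map each score to a
   phenotype class and severity level (`absent < borderline < mild <
   moderate < severe < profound`). Maximal anchor scores map to terminal
   classes: gait 8 → *abasia*, stance 6 → *astasia*, speech 6 → *anarthria*.
3. **Syndrome assessment** — *T* is banded into a categorical
   cerebellar-syndrome assessment (absent / mild / moderate / severe / very
   severe); the absent band *T* ≤ 1 is anchored to the published control
   mean of 0.4 ± 1.1.
4. **Phenotype synopsis** — graded findings are asserted as individuals of
   a scaled-down phenotype ontology (109 subclasses of *phenotypic
   abnormality*, shipped as a plain-text OBO file) and closed upward by
   named-class subsumption: a patient with *abasia* also has *gait ataxia*
   and *truncal (midline) ataxia*. The synopsis summarizes midline ataxia,
   speech impairment, and appendicular ataxia per side, flagging
   asymmetrical syndromes.
5. **Validation harness** — weighted Cohen's kappa
   (κ_w = 1 − Σwᵢⱼoᵢⱼ / Σwᵢⱼeᵢⱼ, linear or quadratic weights) with
   Landis–Koch interpretation bands, plus seeded generators for synthetic
   patient profiles and noisy raters.

All rule tables (severity cut-offs, syndrome bands) are data, not code, and
can be replaced by drop-in YAML files.

## Worked example

Three hypothetical patients share the same total of 20 but differ sharply in
phenotype. Patient 3 combines anarthric speech with a strongly asymmetrical
appendicular syndrome:

```r
library(sarainterp)

ont   <- load_obo(sara_ontology_path())
scale <- load_scale_definition(ont = ont)
rb    <- build_sara_rulebase(scale)

pat <- table1_patients(scale)[[3]]   # gait 2, stance 2, sitting 1, speech 6,
                                     # limbs R/L: 1/4, 1/4, 1/4, 0/3
ev  <- run_pipeline(scale, rb, ont, pat)
cat(ev$report)
```

```
SARA interpretation report for patient patient_3
Total SARA score: 20 / 40
Cerebellar syndrome: present, moderate.

Phenotype synopsis:
  - midline ataxia: mild
  - speech impairment: profound
  - appendicular ataxia (right): mild
  - appendicular ataxia (left): severe
  - asymmetrical involvement of the two sides

Inferred phenotypic abnormalities:
  abnormality_of_movement
  ...
  severe_limb_dysmetria
  sitting_instability
  standing_instability
  tremor
  truncal_ataxia
```

The report says: despite a merely "moderate" total, this patient cannot
speak (speech 6 → *anarthria*, rendered at the top severity rank), and the
left limbs are severely ataxic while the right side is only mildly involved
— exactly the clinical asymmetry the raw total obscures. The same record
exports as JSON/XML payloads (`evaluation_to_json()`,
`evaluation_to_xml()`) and as a node-link phenotype graph
(`evaluation_graph()`).

Agreement between two raters:

```r
tab <- contingency_from_ratings(
  c("mild", "mild", "moderate", "severe", "mild", "moderate"),
  c("mild", "moderate", "moderate", "severe", "mild", "moderate"),
  categories = c("absent", "mild", "moderate", "severe"))
weighted_kappa(tab)
#> weighted kappa (linear): 0.7857  [Substantial]
```

## Command line

A thin front-end ships at `inst/exec/sms`:

```sh
Rscript inst/exec/sms interpret observations.csv --out reports --formats text,json,xml
Rscript inst/exec/sms kappa ratings.csv --categories absent,mild,moderate,severe
Rscript inst/exec/sms extract-module --seeds abasia,anarthria --out module.obo
Rscript inst/exec/sms simulate --n 10 --archetype appendicular_asymmetric --band moderate --seed 1
```

Exit codes: 0 success, 1 validation error, 2 I/O error, 3 configuration
error.

## Package layout

- `R/ontology.R`, `R/obo-io.R`, `R/sara-ontology.R` — ontology container,
  subsumption reasoning, OBO/OWL I/O, the packaged scaled-down ontology.
- `R/scale.R` — SARA content model and observation validation.
- `R/rulebase.R` — staged declarative rules (calculation, severity,
  assessment) and the pipeline.
- `R/synopsis.R` — phenotype inference, synopsis, report, exports.
- `R/agreement.R` — weighted kappa and Landis–Koch bands.
- `R/simdata.R` — worked-example patients, profile and rater simulators.
- `R/cli.R`, `inst/exec/sms` — command-line interface.
- `vignettes/sara-interpretation.Rmd` — the methods vignette (model,
  defaults, design decisions, limitations).
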