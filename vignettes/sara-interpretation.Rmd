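---
title: "Interpreting SARA scores with ontology-backed rules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpreting SARA scores with ontology-backed rules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sarainterp)
```

## The problem

The Scale for the Assessment and Rating of Ataxia (SARA) quantifies
cerebellar dysfunction through eight motor items: gait (0–8), stance (0–6),
sitting (0–4), speech disturbance (0–6), and four limb-coordination tests
(finger chase, nose–finger, fast alternating hand movements, heel–shin;
each 0–4, scored separately for the right and left side). The side means of
the bilateral items are added to the first four scores, so the total

$$T = s_1 + s_2 + s_3 + s_4 + m_5 + m_6 + m_7 + m_8, \qquad
  m_i = \tfrac{s_{iR} + s_{iL}}{2}$$

ranges from 0 (no ataxia) to 40 (most severe ataxia) in half-point steps.

A single number is a blunt summary. Patients with identical totals can
differ in every clinically actionable respect — midline versus appendicular
involvement, intelligible versus absent speech, symmetric versus strongly
lateralized limb ataxia. `sarainterp` recovers that structure by combining
three kinds of knowledge, each held in the representation that fits it:

* a **content model** of the scale (items, ranges, clusters, ontology
  bindings) as a declarative YAML config;
* **procedural knowledge** (score arithmetic, severity cut-offs, syndrome
  banding) as staged, serializable rules;
* **terminological knowledge** (what the graded findings mean and entail)
  as a small phenotype ontology over which the package reasons by
  named-class subsumption.

## The ontology and its reasoning

The ontology is a rooted, acyclic is\_a graph of named classes under a
single `phenotypic_abnormality` root. Reasoning is deliberately minimal:
ancestor closure, seed-based module extraction (the upward closure of a
seed set, yielding a self-contained "slim"), and individual classification
(asserted classes plus all their ancestors). This is exactly the fragment
of description-logic reasoning the interpretation task uses — the
entailments run along the subclass hierarchy, e.g.

```{r}
ont <- sara_ontology()
ancestors(ont, "abasia")
```

so an inability to walk entails gait ataxia and truncal (midline) ataxia.
Equivalence axioms, property restrictions and full OWL-DL consistency
checking are out of scope; the OWL import accordingly reads only asserted
named-class `subClassOf` axioms and counts anything else as skipped.

Severity is modeled as a class-level qualifier: for each severity-graded
class, five subclasses (`borderline_…` to `profound_…`) are generated
deterministically (`<level>_<base id>`), e.g. `moderate_dysarthria` is a
subclass of `dysarthria` with severity `moderate`. The packaged ontology
(`inst/extdata/sara_phenotype_synthetic.obo`) is built programmatically by
`sara_ontology()`: a 29-term cerebellar backbone plus 80 generated severity
subclasses, 109 subclasses of the root in total, matching the published
size of the scaled-down Human Phenotype Ontology module it reconstructs.
It is a synthetic stand-in — the original OWL artifact is not
redistributable here — so class identifiers are readable snake-case labels
rather than HPO accession numbers.

## The rule base

Rules are data, not code: a rule base is built from a severity cut-off
table and a syndrome banding table, validated at build time, and
serializable to YAML so an external cut-off table can be dropped in
verbatim. Three stages fire in fixed order; within a stage, rule conditions
are disjoint, so firing order is irrelevant and the pipeline is
deterministic.

**Calculation** (5 rules): the four bilateral means and the total.

**Severity cut-offs** (35 rules by default, one per item×interval): each
integer score maps to a phenotype class and severity level. The default
binning is

| item | absent | mild | moderate | severe | terminal |
|---|---|---|---|---|---|
| gait | 0 | 1–2 | 3–5 | 6–7 | 8 → abasia |
| stance | 0 | 1–2 | 3–4 | 5 | 6 → astasia |
| sitting | 0 | 1 | 2–3 | 4 | — |
| speech | 0 | 1–2 | 3–4 | 5 | 6 → anarthria |
| limb items (per side) | 0 | 1 | 2–3 | 4 | — |

The anchors with published meaning — sitting 4 → severe sitting
instability, gait 8 → abasia, stance 6 → astasia, speech 6 → anarthria —
are honored; the interior cut-offs are the package's defaults and fully
overridable. Terminal classes denote complete loss of function, so they are
ranked `profound`, the top of the severity order
`absent < borderline < mild < moderate < severe < profound`. Bilateral
items are graded **per side** on the raw integer scores (the means feed
only the total): lateralized findings are what make an asymmetrical
syndrome visible downstream. Build-time validation enumerates every
reachable score of every item and rejects tables leaving a score uncovered
or doubly covered.

**Syndrome assessment** (5 rules): the total is banded as *T* ≤ 1 absent,
(1, 10] mild, (10, 20] moderate, (20, 30] severe, > 30 very severe. The
interpretation of the SARA total is not standardized; the absent band is
anchored to the reported control mean of 0.4 ± 1.1, and the remaining
bounds are package defaults, exposed for override like the cut-offs.

## Synopsis and report

Non-absent findings are asserted as the corresponding severity subclass
when one exists, otherwise as the base class (terminal classes carry no
severity subclasses), and closed upward. The synopsis aggregates findings
per clinical dimension — midline ataxia (gait/stance/sitting), speech
impairment, appendicular ataxia per side — using the **maximum** severity
rank of the member findings: a dimension whose worst component is severe is
a severe problem regardless of the other components, which is how the
worked-example patients are described clinically. A dimension is absent iff
all members are absent. Asymmetry is flagged when the two sides' ranks
differ by ≥ 2 (configurable; the published description flags asymmetry only
qualitatively, so the threshold is a design choice: a one-step difference
is within ordinary rating noise, two steps — e.g. mild vs severe — is not).
Both the per-dimension severity and bare presence are emitted, since either
may be what a consumer needs.

The report renderer is a pure function of the evaluation record
(byte-identical output for identical records), and the record round-trips
losslessly through XML; JSON and DOT/node-link exports accompany it.

## Weighted kappa

The validation harness measures agreement between two raters of ordinal
severity categories with weighted Cohen's kappa,

$$\kappa_w = 1 - \frac{\sum_{ij} w_{ij}\,o_{ij}}{\sum_{ij} w_{ij}\,e_{ij}},
\qquad e_{ij} = \frac{r_i c_j}{n},$$

with linear weights $w_{ij} = |i-j|/(k-1)$ by default (quadratic available
behind a flag; the original analysis does not state its scheme and linear
is the common default for ordinal bands). For $k = 2$ the linear scheme
reduces to unweighted kappa. A table with all mass in one category for both
raters has a zero denominator and is flagged degenerate (κ = 1 when
agreement is perfect, `NA` otherwise). Landis–Koch bands interpret the
value — Poor (< 0), Slight (0–0.20), Fair (0.21–0.40), Moderate
(0.41–0.60), Substantial (0.61–0.80), Almost Perfect (0.81–1.00) — with
boundaries closed on the upper end to match the printed two-decimal ranges:
0.80 is Substantial, 0.81 Almost Perfect.

## What the generators emulate — and what they do not

`table1_patients()` returns the three worked-example patients exactly as
printed (all with *T* = 20).

`generate_profile()` draws random records matching a clinical archetype and
a target band of the total. Archetypes are expressed as per-slot score
caps: `midline_dominant` leaves gait/stance/sitting free but caps speech at
2 and each lateral limb score at 1 (maximum reachable total 18 + 2 + 4 =
24); the appendicular archetypes cap the axial items at 2 each;
`appendicular_asymmetric` additionally caps the unloaded side at 1 per item
and only increments it while the loaded side stays two points ahead, so the
loaded side's limb sum strictly exceeds the other side's in every record.
Scores are built by seeded random unit increments toward a target total
drawn from the band, each increment checked to leave the target reachable.
The generator targets bands rather than exact totals because bands are what
the downstream assessment consumes.

`simulate_raters()` gives each rater the true label with probability
`agreement_prob`, otherwise a label drawn uniformly from the categories
within `drift` ordinal steps of the truth (excluding it). With
`drift ≥ k − 1` the disagreement target is uniform over all other
categories, so `agreement_prob = 1/k` makes the reports independent of the
truth and kappa converges to 0 — the chance-agreement limit the tests
check.

These simulators are structural stand-ins, not disease models: real SCA36
records have correlated item profiles, rater-specific biases and
disease-stage structure that the generators do not attempt to emulate.
Passing the simulation-based tests shows the machinery is correct
(validation, band targeting, kappa recovery), not that the default cut-offs
reproduce expert judgment on real patients — that comparison requires real
paired ratings, which only the harness, not the package, can supply.

## Numerical and testing choices

* Totals move on the half-point grid, exactly representable in doubles; no
  tolerance games are needed and coverage checks enumerate the grid
  exhaustively.
* Acyclicity is checked by Kahn peeling; `ancestors()` is an iterative
  frontier expansion, and the test suite checks it against an independent
  brute-force reachability oracle on random DAGs (up to 200 nodes, fixed
  seeds), the same style of oracle used for weighted kappa (agreement to
  1e-12 on random tables up to k = 5).
* Problem sizes in the tests (200-node DAGs, 5000-pair rater simulations,
  300 asymmetric-profile draws) keep the whole suite under a minute while
  leaving the Monte-Carlo checks comfortably away from their thresholds.
* All generator randomness runs under a locally scoped seed; the caller's
  RNG state is untouched.

## Known limitations

* Only named-class subsumption: no equivalence, disjointness or property
  reasoning; multi-rooted OWL imports must be given a common root first.
* The interior severity cut-offs and the syndrome banding above the absent
  band are package defaults, not published facts; users with a validated
  cut-off table should load it via `build_sara_rulebase(cutoffs = ...)` or
  a YAML rule file.
* Kappa confidence intervals and >2-rater designs (Fleiss) are out of
  scope.
* One assessment date per record; no longitudinal structure.
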