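---
title: "Patient health-factor graphs and the connection delta ratio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patient health-factor graphs and the connection delta ratio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdrgraph)
library(dplyr)
```

## The problem

Electronic medical records (EMRs) hold, for every patient, a trail of
conditions, symptoms, observations, lab results, procedures and medications.
Given a case cohort (patients diagnosed with a target disease, label 1) and
an equally sized control cohort (label 0), a natural question is: *which
health factors in the record are disproportionately attached to the cases?*
`cdrgraph` answers it with a property-graph construction and a simple
ranking statistic, and then splices the patient graph onto a disease
knowledge subgraph extracted from a UMLS-style ontology so that a patient's
actual record can be viewed next to curated biomedical knowledge.

The pipeline has four stages, each usable on its own:

1. **Ingest** — parse the two standardized import tables (patients;
   patient-factor observations), convert continuous values to categories,
   keep only the latest value of each factor per patient, and drop factors
   seen in too few target patients.
2. **Patient graph** — one `Patient` node per cohort member, one node per
   *factor-value pair* `(category, code, converted_value)`, one labeled edge
   per observation (`HAS_CONDITION`, `HAS_LABTEST`, ...).
3. **Ontology subgraph** — parse RRF concept/relation files, expand seed
   disease codes over the hierarchy, keep horizontal relations whose
   relationship attribute is in a curated biological/medical vocabulary,
   and join everything to the patient graph through a single
   `AbstractPatient` node.
4. **CDR analysis** — rank every factor-value node by the connection delta
   ratio and emit the filtered, sorted health-factor distribution.

## The statistic

For a factor-value node let TPC be the number of distinct target patients
connected to it and BPC the number of distinct background patients. The
connection delta ratio is

$$\mathrm{CDR} = \frac{\mathrm{TPC} - \mathrm{BPC}}{\mathrm{TPC} + \mathrm{BPC}} \in [-1, 1].$$

CDR is 1 when a factor is exclusive to the cases, 0 when it is balanced,
negative when it leans toward the controls. It is antisymmetric under
swapping the cohorts, strictly increasing in TPC while BPC > 0 (at BPC = 0
it is pinned at 1, the boundary case), and — the key calibration property —
on equal-size cohorts where a factor attaches to cases with probability
$p_t$ and controls with probability $p_b$, the empirical CDR converges to
$(p_t - p_b)/(p_t + p_b)$. CDR is a descriptive prevalence contrast, not a
test statistic: the package deliberately attaches no p-values or intervals
to it.

A high CDR supported by few connections is fragile, so the distribution
applies two filters with these defaults:

| parameter | default | meaning |
|---|---|---|
| `cdr_cutoff` | 0.5 (strict `>`) | minimum strength of association |
| `min_target_connections` | 10 | minimum distinct target patients (TPC) |
| `excluded_categories` | Procedure, Medication, Treatment | care *of* the disease, not antecedents of it |
| `excluded_patterns` | cancer, carcinoma, neoplasm, tumou?r | drops diagnoses of the disease itself |
| `pattern_categories` | Condition | scope of the pattern blocklist |

A factor with CDR exactly at the cutoff is excluded — the cutoff is a
strict inequality. The pattern blocklist applies only to the `Condition`
category: a cancer *diagnosis* is circular as a risk factor, but a lab
marker that merely carries a carcinoma name (a tumour-antigen assay, say)
is a legitimate finding and stays in. Factors with BPC = 0 (CDR exactly 1)
are retained but flagged with a warning, since zero background connections
can reflect testing bias — a test ordered only on suspicion of the disease
never connects to controls — rather than a true association.

## The synthetic cohort generator

Real hospital extracts cannot ship with a package, so `generate_cohort()`
emulates one with known structure: `n_target` and `n_background` patients
(default 1397 each, the scale of a mid-size single-disease extract) and a
table of factor specs, each attaching independently to every case with
probability `p_t` and every control with probability `p_b`. A single RNG
stream seeded from the config seed makes the two import files byte-stable.

```{r cohort}
specs <- tibble::tibble(
  category = c("RiskFactor", "Symptom"),
  code = c("C-902187", "C-549780"),
  term = c("Smoking", "Pain"),
  converted_value = "true",
  p_t = c(0.7, 0.3), p_b = c(0.2, 0.3)
)
coh <- generate_cohort(cohort_config(specs, n_target = 500, n_background = 500, seed = 7))
coh
```

What the generator does *not* emulate: encounter structure (each synthetic
patient has one deterministic encounter date, so latest-value selection is
exercised by dedicated fixtures instead), correlation between factors,
missingness and coding noise, and the heavy-tailed factor-count
distribution of real EMRs, which no public reference pins down. Passing
tests on synthetic cohorts therefore demonstrate that the machinery
recovers the attachment structure it was given — not that any particular
hospital extract is bias-free.

The mock-ontology generator plays the same role for the RRF side: a
miniature concept file and relation file in the pipe-delimited,
trailing-pipe dialect, defaulting to the eight-concept lung-cancer family
with the hierarchy rooted at the malignant-neoplasm concept.

## Worked example: from cohort to distribution

```{r pipeline}
g <- build_patient_graph(coh$patients, coh$factors)
glance(g)
tidy(g)
```

The smoking factor's empirical CDR sits near the analytic
$(0.7-0.2)/(0.7+0.2) \approx 0.56$; the pain factor, attached equally in
both arms, hovers near 0 and is dropped by the cutoff. The distribution keeps only what clears the filters:

```{r distribution}
d <- build_distribution(g, distribution_config())
d
```

`autoplot(d)` draws the CDR-versus-rank curve; `export_distribution()`
writes the conventional table (category short code, local code, term,
value, CDR to 2 decimals, and an optional literature tag column filled from
a user-supplied map — tagging is a manual literature-review step and is out
of scope here).

## The ontology side

```{r ontology}
rrf <- generate_mock_rrf(mock_ontology_config())
concepts <- parse_mrconso(rrf$mrconso)
relations <- parse_mrrel(rrf$mrrel)
targets <- expand_target_concepts("C0242379", concepts, relations)
targets$term
```

Design choices worth knowing, and why they were made:

* **Hierarchy semantics.** Relation rows are read with REL as the relation
  of the second concept to the first (`CHD` ⇒ CUI2 is a child of CUI1), the
  standard RRF convention, and rows with REL in `PAR`/`CHD` count as
  hierarchical. Expansion defaults to following hierarchy edges in *both*
  directions: the canonical lung-cancer family includes a
  suspected-disease concept that is not a descendant of the
  malignant-neoplasm seed in a strict is-a reading, so a descendants-only
  walk would truncate the family. `direction = "down"`/`"up"` restrict the
  walk for ontologies where one-way closure is wanted. The traversal keeps
  a visited set, so cycles terminate.
* **Relation filtering.** Horizontal candidates are non-hierarchical rows
  touching exactly one target (target-target rows are internal to the
  disease family and excluded). They are kept only if their RELA is in the
  biological or medical vocabulary shipped in
  `inst/extdata/relcat_attributes.yaml` — an editable file, not hard-coded,
  so other diseases can be analysed with adjusted lists. The two lists must
  be disjoint (asserted at load). Bidirectional duplicate rows collapse to
  one undirected record per (target, concept, RELA).
* **Language and preferred terms.** The concept parser keeps one language
  (default `ENG`, configurable) and the first row per CUI in file order as
  the preferred term; only display strings depend on this.
* **Graph model.** `build_integrated_graph()` materialises the fixed
  four-level chain Patient →`INSTANCE_OF`→ AbstractPatient
  →`MAY_HAVE_TARGET`→ TargetConcept →`HAS_RELCAT`→ RelCat →`HAS_RELA`→
  Concept, with one RelCat node per (target, category) pair actually used.
  The single AbstractPatient node is the sole splice point between the EMR
  and ontology sides, so every related concept is within four hops of it.
  `patient_profile()` returns one patient's factors together with that
  chain.

## Ingest rules and degenerate inputs

* Age bins are half-open — `[30,50)`, `[50,70)`, `[70,∞)` — so the
  conventional labels `30-50`, `50-70`, `>70` form a partition; an age
  below 30 is a conversion error rather than a silent drop, since the
  cohorts are defined as aged ≥ 30. Threshold rules use strict `>` (one
  cigarette or one drink per day is `false`).
* Latest-value ties (two observations of a factor on the same date) break
  by file order, last row wins: the choice is arbitrary but documented,
  deterministic, and makes selection idempotent.
* Minimum support counts distinct *target* patients per factor **code**
  (before value splitting); the distribution re-applies the TPC ≥ 10 floor
  at the factor-**value** level, because ranked entries are factor-value
  pairs. Both thresholds are configurable, and the ingest-level filter is
  applied after value conversion.
* Degree-0 factor nodes (possible in hand-built graphs) are allowed but
  never enter CDR computation; a zero-row distribution is a valid result,
  and CDR on TPC + BPC = 0 is an error, never a silent 0.
* Equal CDRs sort by larger TPC, then lexicographic code, so output order
  is reproducible. CDR is computed in double precision — the ratio of
  integers a few thousand in size is exact to well below any reported
  digit — and rounded only at export (2 decimals).

## Graph storage and export

The graph lives in memory as plain tibbles (nodes and an edge list); a
graph database is an export target, never a runtime dependency. Exports:
bulk-import `nodes.csv`/`edges.csv` (round-trips through
`import_graph_csv()` to an isomorphic graph), GraphML via igraph, and a
property-graph statement script with one `CREATE` per node and one
`MATCH ... CREATE` per relationship using the compact property names
(`vpid`, `label`, `cat`, `code`, `valcvt`) that the query examples use.
Queries (`query_patients_with_factors()`) combine clauses disjunctively,
matching the query idiom of clause lists; `match = "all"` gives the
conjunctive variant ("patients holding every one of these factors"). A
clause naming an absent code matches nothing and is reported as a message,
not an error.

## Problem sizes used in the tests

The test-suite checks run at deliberately modest scale: exact CDR
arithmetic on constructed graphs of tens of patients; parameter recovery on
1000 patients per arm over a 20-factor grid with $p_t$ spanning
0–0.9 and $p_b \in \{0.4, 0.8\}$ (pairs chosen so the sampling error of the
empirical CDR stays well inside the 0.05 acceptance band); and oracle
equivalence of the query engine against a brute-force edge-list scan on 200
random graphs of up to a few hundred edges. These sizes make the suite
fast while leaving the binomial concentration arguments comfortably valid.

## Limitations

CDR quantifies prevalence contrast in one extract; it is not causal, it
inherits every sampling and testing bias of the source EMR, and factors
with BPC = 0 deserve particular suspicion. The ontology side implements
streaming-friendly parsing of the RRF dialect but the package has no
ambitions as a general ontology toolkit: no semantic types, no term
normalisation, no licensing or download machinery. Literature verification
of ranked factors is a manual step that the export merely leaves a column
for.
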