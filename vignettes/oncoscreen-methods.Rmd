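---
title: "Screening and matching methods in oncoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening and matching methods in oncoscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncoscreen)
```

`oncoscreen` integrates three sources around a cancer gene panel: a corpus
of clinical-trial registry records, a DrugBank-style drug catalog, and
typed protein–protein interaction (PPI) networks, with a MeSH-derived
neoplasm vocabulary acting as the shared cancer classifier and a zip-code
gazetteer supporting facility proximity filtering. This vignette explains
the procedures, the tunable parameters, and the design decisions taken
where the problem admitted more than one reasonable answer.

## The neoplasm vocabulary

MeSH organizes headings in a tree; every tree number with prefix `C04`
lies in the neoplasms subtree, so the vocabulary is simply the set of
headings carrying at least one `C04`-prefixed tree number
(`neoplasm_vocabulary()`). A heading listed under both a `C04` and a
non-`C04` number (e.g. "Cysts") is included: one cancer-positioned sense
suffices. Deduplication and lookup are case-insensitive.

### Matching headings against free text

Neither registry conditions nor catalog indications use canonical MeSH
strings, so exact equality would classify almost nothing. The matching
scheme is deliberately minimal:

* both sides are lower-cased, list punctuation and hyphens become spaces,
  whitespace is squeezed;
* a heading matches when any of its *variants* occurs in the text as a
  whole-word phrase;
* the variants of an inverted heading ("Leukemia, Lymphocytic, Chronic,
  B-Cell") are the heading itself plus, for each k = n..1, the first k
  comma segments reversed into natural order: "B-Cell Chronic Lymphocytic
  Leukemia", "Chronic Lymphocytic Leukemia", "Lymphocytic Leukemia",
  "Leukemia".

Dropping trailing qualifier segments is what lets the common free-text
form "chronic lymphocytic leukemia (CLL)" hit the fully qualified B-Cell
heading. The k = 1 variant reduces to the head noun ("Leukemia",
"Carcinoma"); for a *binary* cancer classifier this over-triggering is
harmless — any text containing "carcinoma" is a cancer text — but users of
`match_neoplasm_terms()` should expect general headings alongside specific
ones in the returned list. Variants shorter than four characters are never
matched, guarding against degenerate vocabulary entries. Anything beyond
this (synonym folding such as cancer/carcinoma, stemming, UMLS mapping) is
intentionally out of scope: the scheme is centralized in one place
(`heading_variants()`) and easy to revise.

## Trial screening

The four predicates are evaluated independently — no short-circuiting — so
a decision carries *every* failing reason code, which makes corpus-level
audit tables (`screen_corpus()`) meaningful. Decisions of note:

* **Gene mention** searches the concatenation of all textual fields
  (title, conditions, MeSH terms, intervention names, summary, facility
  and contact lines) with a whole-word, case-insensitive match. Word
  boundaries matter: the symbol *ATM* must not fire inside "TREATMENT".
* **Recruiting status** accepts exactly the status "Recruiting". "Not yet
  recruiting", "Enrolling by invitation" and "Active, not recruiting" all
  fail: a patient cannot enrol in any of them today.
* **Country restriction** requires an *actively recruiting* facility in a
  requested country; a trial whose only recruiting sites are abroad fails
  with `NO_LOCATION_IN_COUNTRY` even though its status is "Recruiting".
  A location element without its own recruiting flag inherits the
  trial-level status.
* **User conditions** (e.g. "breast neoplasms, ovarian neoplasms") are an
  additional containment test against the condition subsection only. Each
  supplied label must itself be a neoplasm vocabulary member — anything
  else is a configuration error, caught before any screening happens. A
  trial failing the test is reported under `NOT_CANCER`: the closed
  reason-code set has no dedicated code, and "wrong cancer type" is the
  nearest semantics.

## Drug matching and network expansion

A catalog record is reported for a gene only when three independent gates
pass: the gene is among its targets (exact symbol equality after
upper-casing; no alias resolution), its indication contains a neoplasm
term (*cancer drug*), and its group labels contain none of nutraceutical /
over-the-counter / withdrawn / illicit. Records failing the gates stay in
the catalog — they simply cannot be reached through gene search.

When a gene has no direct hit and `gene_level > 0`, the search expands
breadth-first over *upstream* neighbours. Of the twelve interaction-type
labels in the SIF inputs, the qualifying ones are the directed control
labels (`controls-expression-of`, `controls-state-change-of`,
`controls-phosphorylation-of`, `controls-transport-of`,
`controls-production-of`, `chemical-affects`, `catalysis-precedes`, and
`consumption-controlled-by` with its direction reversed) plus
`in-complex-with`, treated as undirected partnership. `reacts-with`,
`used-to-produce` and `controls-transport-of-chemical` relate molecules
without implying that inhibiting one attenuates the other, and do not
qualify. The rationale is pharmacological: most drugs are antagonists, so
a drug hitting a *regulator* or *complex partner* of the queried gene may
antagonize the gene's activity too — there is no such argument for a
downstream target. The label table is one constant in `R/ppi.R`.

Further expansion decisions:

* the walk *accumulates* hits at every level up to `gene_level` rather
  than stopping at the first level with a hit — deterministic and strictly
  more informative;
* a gene is expanded at most once, at the first level where it is reached,
  so `gene_level = k` costs at most k scans of the edge list per query —
  the exponential growth to fear is in the number of *reported*
  interactors, not in repeated work;
* frontier and output order is lexicographic by symbol, so results are
  reproducible regardless of edge-file order;
* `gene_level = 0` is extensionally identical to the direct search (a
  tested invariant).

The default `gene_level = 1` reflects the interpretability cliff: a drug
two steps removed from the queried gene needs two speculative antagonism
arguments in a row.

## Geographic proximity

Distances are great-circle distances on a sphere (haversine form, with the
arcsine argument clamped to 1 against floating-point overshoot on
near-antipodal points), with the Earth radius fixed per unit: 3959 miles
or 6371 km. The worked pair — zip centroids (40.68, −75.22) and
(39.95, −75.16) — computes to 50.54 miles / 81.33 km, and the suite
cross-checks the implementation against `geosphere::distHaversine` on
random coordinates. Filtering rules: only United States facilities are
ever distance-filtered; a US facility with an empty or unknown zip code is
kept unfiltered (better to over-report a facility than to silently hide
one); `max_distance = 0` is the documented "no filtering" sentinel, and a
positive value requires both an origin zip and the United States among the
selected countries. When filtering leaves a trial with zero facilities the
trial keeps its report rows with a location count of 0 — the filter
reduces facilities, it does not re-adjudicate trial relevance.

## Reports

The summary report has one row per (gene, accepted trial); a gene with
drugs but no accepted trials contributes one drug-only row (dash-filled
trial cells), so catalog knowledge is never lost; a gene with neither
contributes nothing. In the detailed report the drug columns repeat
identically across a gene's trials (a tested invariant), `targeted_genes`
names either the queried gene or the mediating interactors
("CDK7; CDK9"), multi-valued cells join with "; ", empty cells render as
"-", and embedded tabs/newlines are flattened so the files re-import
cleanly with tab as the only delimiter. Row order is panel order, then
trial id, then drug id.

## The synthetic-data generator

`make_trial_corpus()` materializes a *scenario*: n records that all pass
all four predicates by construction, except for a planned number of
records carrying exactly one defect each — not recruiting, non-neoplasm
condition subsection, supplement-only, device-only, or no recruiting US
facility. Screening such a corpus must accept exactly n − (number of
defects), which turns the screening pipeline into something with a known
ground truth; the defect records are placed at seed-determined positions
and generation is byte-deterministic per seed. Free text is templated so
the gene symbol occurs exactly where intended — a clean record differs
from a defective one in precisely one predicate-relevant feature.

The default drug catalog (24 records) and interaction file (21 edges) are
built to exercise every classification path: direct targets, drugs
reachable only through expansion, a nutraceutical, a withdrawn drug, a
non-cancer stimulant, and unannotated probes. Publicly printed drug
accessions are reused where known; the records are nonetheless synthetic,
as is the zip table (the New York entry is placed so that the
five-facility example retains exactly its New York and Pennsylvania
sites within 50 miles of 18042).

What the generator does **not** emulate — and hence what green tests do
not establish about real data: registry free text is far noisier than the
templates (gene symbols that collide with English words, conditions
phrased in neither MeSH nor inverted form); real DrugBank indications are
paragraphs, not single sentences; real PPI exports contain hub genes with
hundreds of neighbours, where expansion output becomes long; and real
corpora contain records failing several predicates at once. The screening
logic is exercised against all of these shapes only in the unit tests,
not by the generator's defaults.

## Problem sizes and determinism

The test suite and the acceptance script run on the scales the scenarios
describe: corpora of 5–20 trials, a 24-record catalog, interaction graphs
of ~20 edges, plus randomized property checks (25-edge random typed
graphs against a brute-force expansion oracle, 20–25 random coordinate
pairs). These sizes keep every check exact and enumerable; nothing in the
implementation is size-bound beyond memory, and the pipeline streams no
state between genes (a tested invariant: removing a panel gene leaves the
other genes' rows byte-identical).

## Known limitations

* Gene symbols are matched verbatim (upper-cased); no HGNC alias or
  history resolution, so a trial writing "HER2" is not found for *ERBB2*.
* The vocabulary matcher can over-trigger on bare head nouns and does not
  bridge lexical gaps (carcinoma vs. cancer) — see above.
* Proximity filtering covers United States zip codes only.
* Prices are reference prices in USD as listed in the catalog; no
  currency or dosage normalization.
* The trial XML dialect is the package's own; an adapter from live
  registry exports is deliberately out of scope, so corpora must be
  prepared offline.
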