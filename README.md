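# oncoscreen

Matching cancer gene panels to clinical trials and targeted drugs, offline.

## The problem

Targeted cancer therapy starts from a patient's mutation profile, usually a
small *cancer gene panel* (e.g. *BRCA1*, *BRCA2*, *PTEN*, *CHEK2*, *EPCAM*,
...). Turning that panel into actionable options means answering two
questions per gene: which actively recruiting drug trials are genuinely
about this gene and this cancer, and which catalogued drugs — approved or
investigational — target the gene's product? Registry keyword search answers
neither precisely: it returns surgery trials, dietary-supplement trials,
device trials and trials that are no longer recruiting. `oncoscreen`
implements a screening-and-integration engine for this task that runs
entirely on local files: a trial corpus (XML), a DrugBank-style drug catalog
(TSV), a MeSH tree file, protein–protein interaction (PPI) networks in SIF
format, and a zip-code coordinate table.

## The method

**Trial screening.** A trial is retained for a queried gene *g* iff all four
predicates hold:

1. *gene mention* — *g* occurs as a whole word anywhere in the record;
2. *cancer trial* — the condition subsection carries at least one MeSH
   heading from the neoplasms subtree (every tree number with prefix
   `C04`), matched case-insensitively with inverted headings
   ("Carcinoma, Non-Small-Cell Lung") reordered to natural word order;
3. *drug intervention* — an intervention of type `drug` with a non-empty
   compound name is listed;
4. *actively recruiting* — overall status is exactly "Recruiting" and, when
   countries are specified, a recruiting facility lies in one of them.

Each rejection carries machine-readable reason codes
(`NO_GENE_MENTION`, `NOT_CANCER`, `NO_DRUG`, `NOT_RECRUITING`,
`NO_LOCATION_IN_COUNTRY`).

**Drug matching.** The queried symbol is matched against the target-gene
field of each catalog record. Only *cancer drugs* are reported: records
whose pharmacology indication contains a neoplasm MeSH term, excluding
nutraceuticals, over-the-counter products, withdrawn and illicit drugs.
When a gene has no direct hit, the search *regresses* up the PPI network:
genes that control the expression, state, phosphorylation, transport or
production of the queried gene, or partner it in a complex, are searched in
turn, breadth-first, up to a configurable gene level (default 1, 0 = off).

**Proximity filtering.** For United States facilities, the great-circle
distance from the user's zip code is computed with the haversine formula

d = 2 r asin( sqrt( sin²((θ₂−θ₁)/2) + cos θ₁ cos θ₂ sin²((λ₂−λ₁)/2) ) )

with r = 3959 miles or 6371 km; facilities farther than the maximum
distance are dropped (facilities abroad, or with unknown zip, are kept
unfiltered; a maximum distance of 0 disables the check).

**Reports.** Each run writes a 7-column `summary.tsv` (gene, trial id,
title, conditions, trial drugs, number of catalog drugs, number of
locations) and a 13-column `detailed.tsv` that additionally repeats, per
trial, the matched drugs with their target genes, reference prices in USD
and known SNP effect/adverse annotations, plus facility contact lines.

## Worked example

```r
library(oncoscreen)
paths <- as.list(make_demo_workspace("demo", seed = 42))
cfg <- run_config(read_gene_panel(paths$panel), gene_level = 1,
                  zip_code = "18042", countries = "United States",
                  max_distance = 50, unit = "miles")
res <- run_pipeline(cfg, paths, "reports")
```

```
panel: BRCA1 EPCAM CHEK2 ATM
trials parsed: 19
BRCA1: 16 accepted, 3 rejected (NO_DRUG=1, NOT_CANCER=1, NOT_RECRUITING=1)
EPCAM: 0 accepted, 19 rejected (NO_GENE_MENTION=19, ...)
```

The synthetic corpus holds 19 breast-cancer trials mentioning *BRCA1*, of
which one is not recruiting, one is a surgical (non-neoplasm) trial and one
has only a dietary-supplement intervention — so 16 survive the four
predicates. The summary report then integrates the drug side:

```
gene   trial_id     title                          ... n_catalog_drugs  n_locations
BRCA1  NCT20042002  A Phase 2 Study of Agent-002 ...    8                1
...
EPCAM  -            -                                   2                0
CHEK2  -            -                                   1                0
ATM    -            -                                   3                0
```

*BRCA1* has no direct cancer drug in the catalog, so the engine expanded
one level up the interaction network and found 8 distinct drugs through its
upstream regulators and complex partners (column `targeted_genes` of the
detailed report names the mediating genes):

```
 drug_id targeted_genes    drug_name
 DB00242    POLE; POLE2   Cladribine
 DB03496     CDK7; CDK9 Flavopiridol
 DB05149   CHEK1; CHEK2        XL844
 DB06616            SRC    Bosutinib
 ...
```

Genes without any accepted trial still contribute drug-only rows (*EPCAM*:
2 direct drugs; *ATM*: 3 drugs via expansion), and `n_locations` counts the
facilities within 50 miles of zip 18042.

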