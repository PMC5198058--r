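Package: oncoscreen
Title: Matching Cancer Gene Panels to Clinical Trials and Targeted Drugs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Screens clinical-trial registry records against a cancer gene
    panel using four eligibility predicates (gene mention, neoplasm MeSH
    condition, drug intervention, active recruitment with optional country
    restriction), matches panel genes to cancer drugs in a DrugBank-style
    catalog either directly or through bounded expansion over typed
    protein-protein interaction networks, filters United States trial
    facilities by great-circle distance from a zip code, and writes
    tab-delimited summary and detailed reports. Includes a deterministic
    synthetic-data generator for every input format.
License: MIT
Encoding: UTF-8
Imports:
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
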