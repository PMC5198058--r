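test_that("trial XML parsing recovers fields, defaults and location flags", {
  corpus <- parse_trials(demo_paths()[["trials"]])
  expect_s3_class(corpus, "trial_corpus")
  expect_length(corpus, 19L)
  t1 <- corpus[[1]]
  expect_match(t1$trial_id, "^NCT[0-9]{8}$")
  expect_equal(t1$phase, "Phase 2")
  expect_equal(t1$locations$country, "United States")
  expect_type(t1$locations$recruiting, "logical")
  ids <- vapply(corpus, `[[`, character(1), "trial_id")
  expect_equal(anyDuplicated(ids), 0L)
})

test_that("trial parsing fails fatally on duplicates, bad XML and empty corpora", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(c("<trials>",
               "<trial><id>NCT1</id><status>Recruiting</status></trial>",
               "<trial><id>NCT1</id><status>Recruiting</status></trial>",
               "</trials>"), f)
  expect_error(parse_trials(f), "duplicate trial id")
  f2 <- withr::local_tempfile(fileext = ".xml")
  writeLines("<trials><trial>", f2)
  expect_error(parse_trials(f2), "malformed")
  f3 <- withr::local_tempfile(fileext = ".xml")
  writeLines("<trials></trials>", f3)
  expect_error(parse_trials(f3), "zero trial records")
})

test_that("a location without a recruiting attribute inherits the trial status", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(c("<trials><trial><id>NCT2</id><status>Recruiting</status>",
               "<location><country>United States</country></location>",
               "<location recruiting=\"false\"><country>Canada</country></location>",
               "</trial><trial><id>NCT3</id><status>Not yet recruiting</status>",
               "<location><country>United States</country></location>",
               "</trial></trials>"), f)
  corpus <- parse_trials(f)
  expect_equal(corpus[[1]]$locations$recruiting, c(TRUE, FALSE))
  expect_false(corpus[[2]]$locations$recruiting)
})

test_that("gene mention requires a whole-word, field-unrestricted hit", {
  trial <- make_trial(summary = "Cohort: somatic mutations in ATM, NBN, BARD1.")
  expect_true(mentions_gene(trial, "ATM"))
  expect_true(mentions_gene(trial, "BARD1"))
  expect_false(mentions_gene(make_trial(title = "TREATMENT of disease",
                                        summary = ""), "ATM"))
  expect_false(mentions_gene(make_trial(summary = "no symbols here"),
                             "BRCA1"))
  # any textual field participates, including intervention names
  iv <- data.frame(type = "drug", name = "anti-EGFR antibody",
                   stringsAsFactors = FALSE)
  expect_true(mentions_gene(make_trial(interventions = iv), "EGFR"))
})

test_that("cancer-trial predicate needs a neoplasm term in the condition subsection", {
  vocab <- default_vocab()
  expect_true(is_cancer_trial(make_trial(
    mesh_terms = c("Breast neoplasms", "triple negative breast neoplasms")),
    vocab))
  expect_false(is_cancer_trial(make_trial(
    conditions = "Breast Reconstruction",
    mesh_terms = c("Pain, Postoperative", "Breast Diseases")), vocab))
  expect_false(is_cancer_trial(make_trial(conditions = character(0),
                                          mesh_terms = character(0)), vocab))
  # condition free-text counts too, not only tagged MeSH terms
  expect_true(is_cancer_trial(make_trial(conditions = "ovarian neoplasms",
                                         mesh_terms = character(0)), vocab))
})

test_that("drug-intervention predicate ignores devices and supplements", {
  iv <- function(type, name) data.frame(type = type, name = name,
                                        stringsAsFactors = FALSE)
  expect_true(has_drug_intervention(make_trial(
    interventions = iv("drug", "Talazoparib tosylate"))))
  expect_true(has_drug_intervention(make_trial(
    interventions = iv("Drug", "x"))))
  expect_false(has_drug_intervention(make_trial(
    interventions = iv("dietary supplement", "Vitamin D"))))
  expect_false(has_drug_intervention(make_trial(
    interventions = iv("device", "Imaging system"))))
  expect_false(has_drug_intervention(make_trial(
    interventions = iv("drug", ""))))
  expect_false(has_drug_intervention(make_trial(
    interventions = iv(character(0), character(0)))))
})

test_that("recruiting predicate combines exact status with country-restricted locations", {
  us <- make_trial()
  expect_true(is_recruiting_in(us, "United States"))
  expect_true(is_recruiting_in(us, character(0)))
  expect_false(is_recruiting_in(make_trial(status = "Active, not recruiting"),
                                "United States"))
  expect_false(is_recruiting_in(make_trial(status = "Not yet recruiting"),
                                character(0)))
  expect_false(is_recruiting_in(make_trial(status = "Enrolling by invitation"),
                                character(0)))
  # recruiting, but the only recruiting location is outside the US
  abroad <- make_trial(locations = data.frame(
    facility = "Site T", city = "Toronto", state = "ON", zip = "",
    country = "Canada", contact = "c@x.org", recruiting = TRUE,
    stringsAsFactors = FALSE))
  expect_false(is_recruiting_in(abroad, "United States"))
  expect_true(is_recruiting_in(abroad, c("United States", "Canada")))
  # a US location that is itself not recruiting does not count
  us_closed <- make_trial(locations = data.frame(
    facility = "Site U", city = "Boston", state = "MA", zip = "02114",
    country = "United States", contact = "c@x.org", recruiting = FALSE,
    stringsAsFactors = FALSE))
  expect_false(is_recruiting_in(us_closed, "United States"))
})

test_that("screening evaluates all predicates and records every failing reason", {
  vocab <- default_vocab()
  ok <- make_trial(summary = "Participants carry BRCA1 variants.")
  d <- screen_trial(ok, "BRCA1", vocab, countries = "United States")
  expect_true(d$accepted)
  expect_length(d$reasons, 0L)

  surgical <- make_trial(summary = "Participants carry BRCA1 variants.",
                         conditions = "Breast Reconstruction",
                         mesh_terms = c("Pain, Postoperative",
                                        "Breast Diseases"))
  expect_equal(screen_trial(surgical, "BRCA1", vocab)$reasons, "NOT_CANCER")

  multi <- make_trial(
    summary = "Participants carry BRCA1 variants.",
    status = "Not yet recruiting",
    interventions = data.frame(type = "device", name = "Scanner",
                               stringsAsFactors = FALSE))
  d2 <- screen_trial(multi, "BRCA1", vocab)
  expect_setequal(d2$reasons, c("NO_DRUG", "NOT_RECRUITING"))
  expect_false(d2$accepted)

  d3 <- screen_trial(ok, "TP53", vocab)
  expect_equal(d3$reasons, "NO_GENE_MENTION")
})

test_that("a multi-gene trial is accepted once per mentioned panel gene", {
  vocab <- default_vocab()
  trial <- make_trial(summary = paste("Cohort with somatic mutations in",
                                      "PTEN, PALB2, CHEK2, ATM, NBN."))
  for (g in c("PTEN", "PALB2", "CHEK2", "ATM", "NBN")) {
    expect_true(screen_trial(trial, g, vocab)$accepted, info = g)
  }
  expect_false(screen_trial(trial, "BRCA1", vocab)$accepted)
})

test_that("user conditions restrict accepted cancer types and must be vocabulary members", {
  vocab <- default_vocab()
  breast <- make_trial(summary = "BRCA1 cohort.")
  ovarian <- make_trial(summary = "BRCA1 cohort.",
                        conditions = "Ovarian Neoplasms",
                        mesh_terms = "Ovarian Neoplasms")
  expect_true(screen_trial(breast, "BRCA1", vocab,
                           conditions = "Breast Neoplasms")$accepted)
  d <- screen_trial(ovarian, "BRCA1", vocab, conditions = "Breast Neoplasms")
  expect_equal(d$reasons, "NOT_CANCER")
  expect_error(screen_trial(breast, "BRCA1", vocab,
                            conditions = "not a cancer term"),
               "not in the neoplasm vocabulary")
})

test_that("corpus screening is order-independent and complete", {
  vocab <- default_vocab()
  corpus <- parse_trials(demo_paths()[["trials"]])
  dec <- screen_corpus(corpus, "BRCA1", vocab, countries = "United States")
  expect_equal(nrow(dec), length(corpus))
  expect_true(all(lengths(dec$reasons[!dec$accepted]) >= 1))
  expect_true(all(lengths(dec$reasons[dec$accepted]) == 0))
  rev_dec <- screen_corpus(structure(rev(unclass(corpus)),
                                     class = "trial_corpus"),
                           "BRCA1", vocab, countries = "United States")
  expect_equal(rev_dec[order(rev_dec$trial_id), "accepted"],
               dec[order(dec$trial_id), "accepted"])
})
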