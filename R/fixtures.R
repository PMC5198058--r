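# Deterministic synthetic-data generators for every input format, including
# scenario builders that inject screening defects with known structure.

DEFECT_CODES <- c("NOT_RECRUITING", "NOT_CANCER", "NO_DRUG",
                  "NO_US_LOCATION", "DEVICE_ONLY")

#' Describe a synthetic trial-corpus scenario
#'
#' A scenario is a corpus of \code{n_trials} records all mentioning one
#' gene, in which a planned number of records carry exactly one screening
#' defect each: \code{NOT_RECRUITING} (status "Not yet recruiting"),
#' \code{NOT_CANCER} (condition subsection tagged only with non-neoplasm
#' terms), \code{NO_DRUG} (dietary-supplement intervention only),
#' \code{DEVICE_ONLY} (device intervention only), \code{NO_US_LOCATION}
#' (recruiting, but all recruiting facilities outside the United States).
#' All other records pass all four screening predicates by construction, so
#' screening the corpus with the United States country filter accepts
#' exactly \code{n_trials - sum(defects)} records.
#'
#' @param seed integer; the same seed yields byte-identical output files.
#' @param n_trials number of records (>= 1).
#' @param defects named integer vector; names from the defect codes above.
#' @param gene HGNC symbol every record mentions.
#' @param condition cancer-type label used as condition and MeSH term of
#'   clean records (must be a neoplasm vocabulary heading for them to pass).
#' @return a \code{scenario_spec} list.
#' @export
scenario_spec <- function(seed, n_trials, defects = integer(0),
                          gene = "BRCA1", condition = "Breast Neoplasms") {
  stopifnot(is.numeric(seed), length(seed) == 1)
  if (n_trials < 1) stop("n_trials must be >= 1", call. = FALSE)
  defects <- defects[defects > 0]
  if (length(defects) > 0) {
    bad <- setdiff(names(defects), DEFECT_CODES)
    if (length(bad) > 0) {
      stop("unknown defect code(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    if (sum(defects) > n_trials) {
      stop("defect plan exceeds n_trials", call. = FALSE)
    }
  }
  structure(list(seed = as.integer(seed), n_trials = as.integer(n_trials),
                 defects = defects, gene = normalize_genes(gene),
                 condition = condition),
            class = "scenario_spec")
}

#' Generate a synthetic trial corpus
#'
#' Materializes a [scenario_spec()] as a trial XML file. Free-text fields
#' are templated so that the gene symbol appears exactly where intended
#' (title and summary) and nowhere else. Defective records are placed at
#' seed-determined positions; generation is fully deterministic, so the
#' same spec always produces a byte-identical file.
#'
#' @param spec a \code{scenario_spec}.
#' @param file output path for the XML file.
#' @return the path, invisibly; the positions and codes of injected defects
#'   are attached as attribute \code{"defect_map"}.
#' @export
make_trial_corpus <- function(spec, file) {
  stopifnot(inherits(spec, "scenario_spec"))
  n <- spec$n_trials
  codes <- rep(names(spec$defects), spec$defects)
  positions <- integer(0)
  if (length(codes) > 0) {
    positions <- withr_seed(spec$seed, sample.int(n, length(codes)))
  }
  defect_at <- stats::setNames(rep("", n), seq_len(n))
  defect_at[positions] <- codes
  lines <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>", "<trials>")
  for (i in seq_len(n)) {
    lines <- c(lines, trial_record_xml(spec, i, defect_at[[i]]))
  }
  lines <- c(lines, "</trials>")
  writeLines(lines, file, useBytes = TRUE)
  out <- invisible(file)
  attr(out, "defect_map") <- data.frame(position = positions, code = codes,
                                        stringsAsFactors = FALSE)
  out
}

# Evaluate expr under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

trial_record_xml <- function(spec, i, defect) {
  id <- sprintf("NCT%08d", 20000000L + (spec$seed %% 8999L) * 1000L + i)
  agent <- sprintf("Agent-%03d", i)
  gene <- spec$gene
  cond <- spec$condition
  status <- if (defect == "NOT_RECRUITING") "Not yet recruiting" else "Recruiting"
  if (defect == "NOT_CANCER") {
    title <- sprintf("A Study of %s for Breast Reconstruction in Patients With %s Mutations",
                     agent, gene)
    conditions <- c("Breast Reconstruction")
    mesh <- c("Pain, Postoperative", "Breast Diseases")
  } else {
    title <- sprintf("A Phase 2 Study of %s in Patients With %s and %s Mutations",
                     agent, cond, gene)
    conditions <- cond
    mesh <- cond
  }
  interventions <- switch(defect,
    NO_DRUG = "    <intervention type=\"dietary supplement\">Vitamin D Supplement</intervention>",
    DEVICE_ONLY = "    <intervention type=\"device\">Tomographic Imaging System</intervention>",
    sprintf("    <intervention type=\"drug\">%s</intervention>", agent))
  if (defect == "NO_US_LOCATION") {
    location <- c(
      "    <location recruiting=\"true\">",
      sprintf("      <facility>Toronto General Research Institute Site %03d</facility>", i),
      "      <city>Toronto</city>", "      <state>Ontario</state>",
      "      <zip></zip>", "      <country>Canada</country>",
      sprintf("      <contact>coordinator%03d@example.org, 555-0188</contact>", i),
      "    </location>")
  } else {
    # explicit recruiting attribute so a status defect breaks only the
    # status predicate, never the country predicate
    location <- c(
      "    <location recruiting=\"true\">",
      sprintf("      <facility>University Medical Center %03d</facility>", i),
      "      <city>Allentown</city>", "      <state>Pennsylvania</state>",
      "      <zip>18102</zip>", "      <country>United States</country>",
      sprintf("      <contact>coordinator%03d@example.org, 555-0142</contact>", i),
      "    </location>")
  }
  c("  <trial>",
    sprintf("    <id>%s</id>", id),
    sprintf("    <title>%s</title>", title),
    sprintf("    <status>%s</status>", status),
    "    <phase>Phase 2</phase>",
    sprintf("    <condition>%s</condition>", conditions),
    sprintf("    <mesh_term>%s</mesh_term>", mesh),
    interventions,
    sprintf("    <summary>This study evaluates %s in participants carrying pathogenic %s variants detected by panel sequencing.</summary>",
            agent, gene),
    location,
    "  </trial>")
}

#' Default synthetic drug-catalog entries
#'
#' A compact catalog exercising every classification path: approved and
#' investigational cancer drugs with known gene targets and reference
#' prices, kinase inhibitors reachable only through interaction-network
#' expansion, a nutraceutical, a withdrawn drug, a non-cancer stimulant and
#' unannotated chemical probes. Drug ids that are printed in public
#' catalogs are used where known; the records themselves are synthetic.
#'
#' @return a data.frame in the catalog TSV column layout (all character).
#' @export
default_drug_entries <- function() {
  e <- function(id, type, name, brands, syns, prices, ind, targets, eff,
                adv, groups, desc) {
    data.frame(drug_id = id, molecule_type = type, name = name,
               brand_names = brands, synonyms = syns, prices = prices,
               indication = ind, target_genes = targets, snp_effects = eff,
               snp_adverse = adv, groups = groups, description = desc,
               stringsAsFactors = FALSE)
  }
  atp_targets <- paste(c("ABL1", sprintf("NTP%02d", 1:32)), collapse = ";")
  rbind(
    e("DB00317", "small molecule", "Gefitinib", "Iressa;Tarceva",
      "ZD 1839",
      "Tarceva 25 mg tablet USD 52.78;Iressa 250 mg tablet USD 68.08;Tarceva 100 mg tablet USD 144.98;Tarceva 150 mg tablet USD 163.98",
      "For the treatment of metastatic non-small-cell lung carcinoma.",
      "EGFR",
      "G719A/C in EGFR increases sensitivity in non-small-cell lung carcinoma patients",
      "-", "approved", "EGFR tyrosine kinase inhibitor."),
    e("DB05149", "small molecule", "XL844", "", "",
      "",
      "Investigational agent for the treatment of chronic lymphocytic leukemia (CLL).",
      "CHEK1;CHEK2", "-", "-", "investigational",
      "Checkpoint kinase inhibitor."),
    e("DB03496", "small molecule", "Flavopiridol", "Alvocidib", "HMR 1275",
      "",
      "Treatment of esophageal neoplasms, lung neoplasms, liver neoplasms and lymphoid leukemia.",
      "CDK7;CDK9", "-", "-", "experimental",
      "Pan-cyclin-dependent kinase inhibitor."),
    e("DB00242", "small molecule", "Cladribine", "Leustatin", "2-CdA",
      "Leustatin 1 mg/mL vial USD 28.00",
      "For the treatment of chronic lymphocytic leukemia and hairy cell leukemia.",
      "POLE;POLE2", "-", "-", "approved",
      "Purine nucleoside antimetabolite."),
    e("DB05319", "biotech", "Oportuzumab monatox", "Vicinium", "VB4-845",
      "",
      "Investigated for the treatment of urinary bladder neoplasms.",
      "EPCAM", "-", "-", "investigational",
      "Anti-EpCAM immunotoxin fusion protein."),
    e("DB05831", "biotech", "ING-1", "", "",
      "",
      "Intended for the treatment of breast neoplasms and ovarian neoplasms.",
      "EPCAM", "-", "-", "investigational",
      "High-affinity anti-EpCAM monoclonal antibody."),
    e("DB06616", "small molecule", "Bosutinib", "Bosulif", "SKI-606",
      "Bosulif 100 mg tablet USD 91.67",
      "For the treatment of chronic myelogenous leukemia with resistance to prior therapy.",
      "ABL1;SRC", "-", "-", "approved", "Dual SRC/ABL kinase inhibitor."),
    e("DB01254", "small molecule", "Dasatinib", "Sprycel", "BMS-354825",
      "Sprycel 50 mg tablet USD 137.04",
      "For the treatment of chronic myelogenous leukemia and Philadelphia-positive acute lymphoblastic leukemia.",
      "ABL1", "-", "-", "approved", "Second-generation ABL kinase inhibitor."),
    e("DB00619", "small molecule", "Imatinib", "Gleevec", "STI-571",
      "Gleevec 100 mg tablet USD 34.36",
      "For the treatment of chronic myelogenous leukemia and gastrointestinal stromal tumors.",
      "ABL1;KIT", "-", "-", "approved", "Prototype BCR-ABL inhibitor."),
    e("DB04868", "small molecule", "Nilotinib", "Tasigna", "AMN107",
      "Tasigna 200 mg capsule USD 48.48",
      "For the treatment of chronic myelogenous leukemia.",
      "ABL1", "-",
      "UGT1A1 *28 homozygotes at increased risk of hyperbilirubinemia",
      "approved", "Aminopyrimidine ABL inhibitor."),
    e("DB08901", "small molecule", "Ponatinib", "Iclusig", "AP24534",
      "",
      "For the treatment of chronic myelogenous leukemia with the T315I mutation.",
      "ABL1", "-", "-", "approved", "Third-generation pan-ABL inhibitor."),
    e("DB08896", "small molecule", "Regorafenib", "Stivarga", "BAY 73-4506",
      "",
      "For the treatment of metastatic colorectal neoplasms.",
      "ABL1;KDR", "-", "-", "approved", "Multi-kinase inhibitor."),
    e("DB05987", "small molecule", "XL228", "", "",
      "",
      "Experimental agent for acute lymphoblastic leukemia.",
      "ABL1;IGF1R", "-", "-", "experimental",
      "IGF1R/ABL/SRC-family inhibitor in early development."),
    e("DB07145", "small molecule", "AT7519", "", "",
      "",
      "Investigated for the treatment of multiple myeloma and chronic lymphocytic leukemia.",
      "CDK1;CDK2", "-", "-", "investigational",
      "Multi-CDK inhibitor."),
    e("DB11920", "small molecule", "MLN8237", "", "Alisertib",
      "",
      "Investigated for the treatment of lung neoplasms and lymphoid leukemia.",
      "AURKA", "-", "-", "investigational", "Aurora A kinase inhibitor."),
    e("DB11921", "small molecule", "AT9283", "", "",
      "",
      "Investigated for the treatment of multiple myeloma.",
      "AURKA;AURKB", "-", "-", "investigational",
      "Aurora/JAK kinase inhibitor."),
    e("DB11922", "small molecule", "CYC116", "", "",
      "",
      "Investigated for the treatment of advanced solid neoplasms.",
      "AURKA;AURKB", "-", "-", "investigational",
      "Aurora kinase inhibitor."),
    e("DB11760", "small molecule", "Talazoparib", "Talzenna", "BMN-673",
      "Talzenna 1 mg capsule USD 527.00",
      "For the treatment of advanced breast neoplasms with germline BRCA mutations.",
      "PARP1;PARP2", "-", "-", "approved", "PARP inhibitor with trapping activity."),
    e("DB00201", "small molecule", "Caffeine", "", "1,3,7-Trimethylxanthine",
      "",
      "A central nervous system stimulant used to restore mental alertness.",
      "ATM", "-", "-", "approved", "Methylxanthine stimulant."),
    e("DB00171", "small molecule", "Adenosine triphosphate", "", "ATP",
      "",
      "For nutritional supplementation in parenteral feeding.",
      atp_targets, "-", "-", "nutraceutical",
      "Ubiquitous nucleotide cofactor."),
    e("DB01041", "small molecule", "Thalidomide", "Thalomid", "",
      "",
      "For the treatment of multiple myeloma.",
      "TNF", "-", "-", "approved;withdrawn",
      "Immunomodulatory agent withdrawn after teratogenicity."),
    e("DB08043", "small molecule",
      "1-[4-(Pyridin-4-yloxy)phenyl]-3-[3-(trifluoromethyl)phenyl]urea",
      "", "", "", "", "ABL1", "-", "-", "experimental",
      "Chemical probe without annotated indication."),
    e("DB07831", "small molecule",
      "2-{[(6-Oxo-1,6-dihydropyridin-3-yl)methyl]amino}-N-[4-propyl-3-(trifluoromethyl)phenyl]benzamide",
      "", "", "", "", "ABL1", "-", "-", "experimental",
      "Chemical probe without annotated indication."),
    e("DB08350", "small molecule",
      "5-[3-(2-Methoxyphenyl)-1H-pyrrolo[2,3-b]pyridin-5-yl]-N,N-dimethylpyridine-3-carboxamide",
      "", "", "", "", "ABL1", "-", "-", "experimental",
      "Chemical probe without annotated indication.")
  )
}

#' Write a drug-catalog TSV file
#'
#' @param file output path.
#' @param entries data.frame in the catalog column layout; defaults to
#'   [default_drug_entries()].
#' @return the path, invisibly.
#' @export
make_catalog <- function(file, entries = default_drug_entries()) {
  stopifnot(identical(names(entries), CATALOG_COLUMNS))
  utils::write.table(entries, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(file)
}

#' Write a MeSH tree fixture file
#'
#' The default entries cover the neoplasm headings used by the default
#' catalog and corpora (general terms, breast/ovarian/lung/colorectal/
#' bladder neoplasms, the leukemia headings in inverted MeSH form, a
#' duplicated heading carried by both a C04 and a non-C04 tree number) plus
#' non-neoplasm distractors.
#'
#' @param file output path.
#' @param entries optional data.frame with \code{heading},
#'   \code{tree_number}.
#' @return the path, invisibly.
#' @export
make_mesh_file <- function(file, entries = default_mesh_entries()) {
  writeLines(c("# heading;tree_number",
               paste(entries$heading, entries$tree_number, sep = ";")),
             file, useBytes = TRUE)
  invisible(file)
}

#' @rdname make_mesh_file
#' @export
default_mesh_entries <- function() {
  m <- matrix(c(
    "Neoplasms", "C04",
    "Cysts", "C04.182",
    "Cysts", "C23.300.306",
    "Bone Cysts", "C04.182.044",
    "Breast Neoplasms", "C04.588.180",
    "Triple Negative Breast Neoplasms", "C04.588.180.788",
    "Ovarian Neoplasms", "C04.588.322.455",
    "Carcinoma", "C04.557.470.200",
    "Cystadenocarcinoma", "C04.557.470.200.220",
    "Carcinoma, Non-Small-Cell Lung", "C04.588.894.797.520.109.220.249",
    "Leukemia", "C04.557.337",
    "Leukemia, Lymphocytic, Chronic, B-Cell", "C04.557.337.428.080.125",
    "Leukemia, Myelogenous, Chronic, BCR-ABL Positive", "C04.557.337.539.250",
    "Precursor Cell Lymphoblastic Leukemia-Lymphoma", "C04.557.337.428.600",
    "Esophageal Neoplasms", "C04.588.443.353",
    "Lung Neoplasms", "C04.588.894.797.520",
    "Liver Neoplasms", "C04.588.274.623",
    "Colorectal Neoplasms", "C04.588.274.476.411.307",
    "Urinary Bladder Neoplasms", "C04.588.945.947.960",
    "Multiple Myeloma", "C04.557.595.500",
    "Heart Diseases", "C14.280",
    "Breast Diseases", "C17.800.090",
    "Pain, Postoperative", "C23.888.592.612.944",
    "Ataxia Telangiectasia", "C10.228.140.252.190.530"
  ), ncol = 2, byrow = TRUE)
  data.frame(heading = m[, 1], tree_number = m[, 2], stringsAsFactors = FALSE)
}

#' Write a SIF interaction fixture file
#'
#' The default edge set places CDK2/CDK7/CDK9 (state-change / expression
#' control), the Aurora kinases, the checkpoint kinases, the POLE
#' polymerase subunits and SRC upstream of BRCA1, and POLE/POLE2/CDK7/CDK9/
#' CHEK1/CHEK2 upstream of ATM, together with downstream and non-qualifying
#' edges used to exercise the direction rules.
#'
#' @param file output path.
#' @param edges optional data.frame with \code{source}, \code{type},
#'   \code{target}.
#' @return the path, invisibly.
#' @export
make_sif_file <- function(file, edges = default_sif_edges()) {
  writeLines(paste(edges$source, edges$type, edges$target, sep = "\t"),
             file, useBytes = TRUE)
  invisible(file)
}

#' @rdname make_sif_file
#' @export
default_sif_edges <- function() {
  m <- matrix(c(
    "CDK2", "controls-state-change-of", "BRCA1",
    "CDK7", "controls-expression-of", "BRCA1",
    "CDK9", "controls-expression-of", "BRCA1",
    "AURKA", "controls-phosphorylation-of", "BRCA1",
    "AURKB", "in-complex-with", "BRCA1",
    "CHEK1", "controls-phosphorylation-of", "BRCA1",
    "CHEK2", "controls-phosphorylation-of", "BRCA1",
    "POLE", "in-complex-with", "BRCA1",
    "POLE2", "in-complex-with", "BRCA1",
    "SRC", "controls-phosphorylation-of", "BRCA1",
    "POLE", "in-complex-with", "ATM",
    "POLE2", "in-complex-with", "ATM",
    "CDK7", "controls-phosphorylation-of", "ATM",
    "CDK9", "controls-phosphorylation-of", "ATM",
    "CHEK1", "in-complex-with", "ATM",
    "CHEK2", "controls-state-change-of", "ATM",
    "BRCA1", "controls-expression-of", "ESR1",
    "UBE2D1", "used-to-produce", "BRCA1",
    "MDM2", "controls-state-change-of", "TP53",
    "EP300", "controls-state-change-of", "CDK2",
    "KAT2B", "controls-expression-of", "EP300"
  ), ncol = 3, byrow = TRUE)
  data.frame(source = m[, 1], type = m[, 2], target = m[, 3],
             stringsAsFactors = FALSE)
}

#' Write a zip-code coordinate fixture table
#'
#' Includes the eastern-Pennsylvania pair 18042 (40.68, -75.22) and 19019
#' (39.95, -75.16) used by the worked distance example, plus facility zips
#' in five states. The table is synthetic: the New York entry is placed so
#' that exactly the New York and Pennsylvania facilities of the
#' five-facility example fall within 50 miles of 18042.
#'
#' @param file output path.
#' @param table optional data.frame with \code{zip}, \code{latitude},
#'   \code{longitude}.
#' @return the path, invisibly.
#' @export
make_zip_table <- function(file, table = default_zip_table()) {
  utils::write.table(table, file, sep = ",", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(file)
}

#' @rdname make_zip_table
#' @export
default_zip_table <- function() {
  data.frame(
    zip = c("18042", "19019", "18102", "10940", "10021", "94305", "02114",
            "77030"),
    latitude = c(40.68, 39.95, 40.60, 41.05, 40.77, 37.42, 42.36, 29.70),
    longitude = c(-75.22, -75.16, -75.47, -74.75, -73.96, -122.17, -71.07,
                  -95.40),
    stringsAsFactors = FALSE
  )
}

#' Materialize a complete demo workspace
#'
#' Writes all six input files (gene panel, trial corpus, drug catalog, MeSH
#' tree, SIF interactions, zip table) into a directory, ready for
#' [run_pipeline()].
#'
#' @param dir target directory (created if absent).
#' @param seed integer seed controlling the trial corpus.
#' @return named character vector of the file paths, invisibly.
#' @export
make_demo_workspace <- function(dir, seed = 42L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    panel = file.path(dir, "panel.txt"),
    trials = file.path(dir, "trials.xml"),
    catalog = file.path(dir, "catalog.tsv"),
    mesh = file.path(dir, "mesh.txt"),
    sif = file.path(dir, "interactions.sif"),
    zips = file.path(dir, "zips.csv")
  )
  writeLines("BRCA1 EPCAM CHEK2\nATM", paths[["panel"]])
  make_trial_corpus(
    scenario_spec(seed, n_trials = 19,
                  defects = c(NOT_RECRUITING = 1, NOT_CANCER = 1,
                              NO_DRUG = 1),
                  gene = "BRCA1", condition = "Breast Neoplasms"),
    paths[["trials"]])
  make_catalog(paths[["catalog"]])
  make_mesh_file(paths[["mesh"]])
  make_sif_file(paths[["sif"]])
  make_zip_table(paths[["zips"]])
  invisible(paths)
}
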