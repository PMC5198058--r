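# DrugBank-style catalog: parsing, cancer-drug classification, eligibility,
# and gene-keyed drug lookup.

CATALOG_COLUMNS <- c("drug_id", "molecule_type", "name", "brand_names",
                     "synonyms", "prices", "indication", "target_genes",
                     "snp_effects", "snp_adverse", "groups", "description")

EXCLUDED_GROUPS <- c("nutraceutical", "over-the-counter", "withdrawn",
                     "illicit")

#' Parse a drug-catalog TSV file
#'
#' Reads a headered tab-separated drug catalog with one drug per row.
#' Multi-valued cells (brand names, synonyms, prices, target genes, groups)
#' are \code{";"}-joined in the file and split on read. Each price entry must
#' end with \code{"USD <amount>"}; the leading text is the label (e.g.
#' \code{"Tarceva 25 mg tablet USD 52.78"}). Unparseable price entries are
#' dropped with a warning. Target gene symbols are upper-cased and
#' deduplicated.
#'
#' @param file path to the catalog TSV.
#' @return an object of class \code{drug_catalog}: a list with
#'   \code{records} (a data.frame with list-columns for multi-valued fields),
#'   and empty \code{cancer_ids} / \code{gene_index} until
#'   [index_catalog()] is called.
#' @export
parse_drug_catalog <- function(file) {
  if (!file.exists(file)) {
    stop("drug catalog file not found: ", file, call. = FALSE)
  }
  raw <- utils::read.delim(file, colClasses = "character", quote = "",
                           check.names = FALSE, stringsAsFactors = FALSE)
  missing_cols <- setdiff(CATALOG_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    stop("drug catalog is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0) {
    stop("drug catalog contains no records: ", file, call. = FALSE)
  }
  ids <- trimws(raw$drug_id)
  if (anyDuplicated(ids)) {
    stop("duplicate drug_id in catalog: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (any(!grepl("^DB[0-9]+$", ids))) {
    warning("drug_id(s) not matching 'DB' + digits: ",
            paste(ids[!grepl("^DB[0-9]+$", ids)], collapse = ", "),
            call. = FALSE)
  }
  records <- data.frame(
    drug_id = ids,
    molecule_type = trimws(raw$molecule_type),
    name = trimws(raw$name),
    indication = trimws(raw$indication),
    snp_effects = trimws(raw$snp_effects),
    snp_adverse = trimws(raw$snp_adverse),
    description = trimws(raw$description),
    stringsAsFactors = FALSE
  )
  records$brand_names <- lapply(raw$brand_names, split_multi)
  records$synonyms <- lapply(raw$synonyms, split_multi)
  records$target_genes <- lapply(raw$target_genes,
                                 function(x) unique(normalize_genes(split_multi(x))))
  records$groups <- lapply(raw$groups, function(x) tolower(split_multi(x)))
  records$prices <- lapply(raw$prices, parse_prices)
  structure(list(records = records,
                 cancer_ids = character(0),
                 gene_index = list()),
            class = "drug_catalog")
}

# Parse a ";"-joined price cell into a data.frame(label, amount_usd).
parse_prices <- function(cell) {
  entries <- split_multi(cell)
  labels <- character(0)
  amounts <- numeric(0)
  for (e in entries) {
    m <- regmatches(e, regexec("^(.*\\S)\\s+USD\\s+([0-9]+(?:\\.[0-9]+)?)$", e))[[1]]
    if (length(m) == 3) {
      labels <- c(labels, m[2])
      amounts <- c(amounts, as.numeric(m[3]))
    } else {
      warning("unparseable price entry dropped: '", e, "'", call. = FALSE)
    }
  }
  data.frame(label = labels, amount_usd = amounts, stringsAsFactors = FALSE)
}

#' Is a drug a cancer drug?
#'
#' A catalog record is classified as a cancer drug when its pharmacology
#' indication text contains at least one neoplasm MeSH heading (the C04
#' subtree), via [match_neoplasm_terms()].
#'
#' @param record one row of \code{catalog$records} (data.frame of one row).
#' @param vocab a \code{neoplasm_vocab}.
#' @return logical scalar.
#' @export
classify_cancer_drug <- function(record, vocab) {
  length(match_neoplasm_terms(record$indication, vocab)) > 0
}

#' Is a drug eligible for reporting?
#'
#' Drugs labelled nutraceutical, over-the-counter, withdrawn, or illicit are
#' excluded from every gene-keyed search; everything else (approved,
#' experimental, investigational, ...) is eligible.
#'
#' @param record one row of \code{catalog$records}.
#' @return logical scalar.
#' @export
drug_is_eligible <- function(record) {
  groups <- tolower(unlist(record$groups))
  groups <- gsub("[ _]", "-", groups)
  !any(groups %in% EXCLUDED_GROUPS)
}

#' Build the cancer-drug and gene indexes of a catalog
#'
#' Flags as cancer drugs the records that are both classified as cancer
#' drugs (neoplasm term in the indication) and eligible (not excluded by
#' group label), and builds the gene index mapping every target gene symbol
#' to the ids of records targeting it.
#'
#' @param catalog a \code{drug_catalog} from [parse_drug_catalog()].
#' @param vocab a \code{neoplasm_vocab}.
#' @return the catalog with \code{cancer_ids} and \code{gene_index} filled.
#' @export
index_catalog <- function(catalog, vocab) {
  stopifnot(inherits(catalog, "drug_catalog"))
  recs <- catalog$records
  is_cancer <- vapply(seq_len(nrow(recs)), function(i) {
    classify_cancer_drug(recs[i, ], vocab) && drug_is_eligible(recs[i, ])
  }, logical(1))
  catalog$cancer_ids <- recs$drug_id[is_cancer]
  idx <- list()
  for (i in seq_len(nrow(recs))) {
    for (g in recs$target_genes[[i]]) {
      idx[[g]] <- c(idx[[g]], recs$drug_id[i])
    }
  }
  catalog$gene_index <- idx
  catalog
}

#' Cancer drugs targeting a gene
#'
#' Looks up the catalog records whose target-gene list contains the queried
#' symbol (exact, case-insensitive equality) and that are flagged as cancer
#' drugs. Results are sorted by drug id.
#'
#' @param gene an HGNC gene symbol.
#' @param catalog an indexed \code{drug_catalog} (see [index_catalog()]).
#' @return a data.frame of matching records (possibly zero rows).
#' @export
drugs_targeting <- function(gene, catalog) {
  stopifnot(inherits(catalog, "drug_catalog"))
  if (length(catalog$gene_index) == 0 && length(catalog$cancer_ids) == 0) {
    stop("catalog indexes not built; call index_catalog() first",
         call. = FALSE)
  }
  gene <- normalize_genes(gene)
  ids <- catalog$gene_index[[gene]] %||% character(0)
  ids <- sort(intersect(ids, catalog$cancer_ids))
  catalog$records[match(ids, catalog$records$drug_id), , drop = FALSE]
}

#' @export
print.drug_catalog <- function(x, ...) {
  cat("Drug catalog:", nrow(x$records), "records;",
      length(x$cancer_ids), "flagged cancer drugs;",
      length(x$gene_index), "indexed target genes\n")
  invisible(x)
}
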