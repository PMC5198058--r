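# Per-gene integration of screened trials and matched drugs, and the two
# tab-delimited reports (summary: 7 columns, detailed: 13 columns).

SUMMARY_HEADER <- c("gene", "trial_id", "title", "conditions", "trial_drugs",
                    "n_catalog_drugs", "n_locations")
DETAIL_HEADER <- c("gene", "trial_id", "title", "phase", "conditions",
                   "trial_drugs", "drug_id", "targeted_genes", "drug_name",
                   "prices", "snp_effects", "snp_adverse",
                   "locations_contact")

#' Build the integrated report for one gene
#'
#' Resolves the gene's drug matches (directly, or through interaction-
#' network expansion when no direct cancer drug exists and the gene level is
#' positive), applies facility proximity filtering to the accepted trials,
#' and emits the cross-product rows for the detailed report plus one summary
#' row per accepted trial. A gene with trials but no drugs emits trial rows
#' with \code{"-"} drug cells; a gene with drugs but no accepted trials
#' emits one drug-only summary row and one detail row per drug; a gene with
#' neither emits nothing.
#'
#' @param gene queried HGNC gene symbol.
#' @param accepted_trials list of accepted trial records for this gene.
#' @param catalog an indexed \code{drug_catalog}.
#' @param graph an \code{interaction_graph} (may be NULL when
#'   \code{gene_level = 0}).
#' @param config a \code{run_config} (gene level, zip, distance, unit).
#' @param zip_table a \code{zip_table}, required when proximity filtering is
#'   active.
#' @return an object of class \code{gene_report}: list with \code{gene},
#'   \code{drugs} (data.frame incl. \code{via_genes}), \code{expanded}
#'   (logical), \code{summary} and \code{detail} data.frames.
#' @export
build_gene_report <- function(gene, accepted_trials, catalog, graph = NULL,
                              config = run_config(genes = gene),
                              zip_table = NULL) {
  gene <- normalize_genes(gene)
  direct <- drugs_targeting(gene, catalog)
  expanded <- FALSE
  if (nrow(direct) > 0 || config$gene_level == 0 || is.null(graph)) {
    drugs <- direct
    drugs$via_genes <- rep(gene, nrow(direct))
  } else {
    expansion <- expand_gene_search(gene, config$gene_level, graph, catalog)
    drugs <- expansion_drugs(expansion)
    expanded <- nrow(drugs) > 0
  }
  summary_rows <- list()
  detail_rows <- list()
  drug_cells <- drug_report_cells(drugs)
  for (trial in accepted_trials) {
    locs <- trial$locations
    if (config$max_distance > 0 && !is.null(zip_table)) {
      locs <- facilities_within(locs, config$zip_code, config$max_distance,
                                config$unit, zip_table)
    }
    contact <- paste(apply(locs, 1, function(r)
      paste(r[c("facility", "city", "state", "zip", "country", "contact")]
            [nzchar(r[c("facility", "city", "state", "zip", "country",
                        "contact")])], collapse = ", ")), collapse = " | ")
    summary_rows[[length(summary_rows) + 1L]] <- data.frame(
      gene = gene, trial_id = trial$trial_id, title = trial$title,
      conditions = paste(trial$conditions, collapse = "; "),
      trial_drugs = paste(trial$interventions$name[
        tolower(trial$interventions$type) == "drug"], collapse = "; "),
      n_catalog_drugs = nrow(drugs), n_locations = nrow(locs),
      stringsAsFactors = FALSE)
    base <- data.frame(
      gene = gene, trial_id = trial$trial_id, title = trial$title,
      phase = trial$phase,
      conditions = paste(trial$conditions, collapse = "; "),
      trial_drugs = paste(trial$interventions$name[
        tolower(trial$interventions$type) == "drug"], collapse = "; "),
      stringsAsFactors = FALSE)
    if (nrow(drug_cells) == 0) {
      detail_rows[[length(detail_rows) + 1L]] <-
        cbind(base, empty_drug_cells(), locations_contact = contact,
              stringsAsFactors = FALSE)
    } else {
      for (i in seq_len(nrow(drug_cells))) {
        detail_rows[[length(detail_rows) + 1L]] <-
          cbind(base, drug_cells[i, , drop = FALSE],
                locations_contact = contact, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(accepted_trials) == 0 && nrow(drug_cells) > 0) {
    # drug-only gene: no trial, but catalog knowledge is still reported
    summary_rows[[1L]] <- data.frame(
      gene = gene, trial_id = "-", title = "-", conditions = "-",
      trial_drugs = "-", n_catalog_drugs = nrow(drugs), n_locations = 0L,
      stringsAsFactors = FALSE)
    base <- data.frame(gene = gene, trial_id = "-", title = "-",
                       phase = "-", conditions = "-", trial_drugs = "-",
                       stringsAsFactors = FALSE)
    for (i in seq_len(nrow(drug_cells))) {
      detail_rows[[length(detail_rows) + 1L]] <-
        cbind(base, drug_cells[i, , drop = FALSE], locations_contact = "-",
              stringsAsFactors = FALSE)
    }
  }
  summary <- if (length(summary_rows)) do.call(rbind, summary_rows) else
    stats::setNames(data.frame(matrix(character(0), ncol = 7),
                               stringsAsFactors = FALSE), SUMMARY_HEADER)
  detail <- if (length(detail_rows)) do.call(rbind, detail_rows) else
    stats::setNames(data.frame(matrix(character(0), ncol = 13),
                               stringsAsFactors = FALSE), DETAIL_HEADER)
  rownames(summary) <- rownames(detail) <- NULL
  structure(list(gene = gene, drugs = drugs, expanded = expanded,
                 summary = summary, detail = detail),
            class = "gene_report")
}

# Columns G-L of the detailed report for each matched drug.
drug_report_cells <- function(drugs) {
  if (nrow(drugs) == 0) {
    return(data.frame(drug_id = character(0), targeted_genes = character(0),
                      drug_name = character(0), prices = character(0),
                      snp_effects = character(0), snp_adverse = character(0),
                      stringsAsFactors = FALSE))
  }
  prices <- vapply(drugs$prices, function(p) {
    if (is.null(p) || nrow(p) == 0) return("-")
    paste(sprintf("%s USD %.2f", p$label, p$amount_usd), collapse = "; ")
  }, character(1))
  dash <- function(x) ifelse(is.na(x) | !nzchar(trimws(x)), "-", x)
  data.frame(
    drug_id = drugs$drug_id,
    targeted_genes = dash(drugs$via_genes),
    drug_name = drugs$name,
    prices = prices,
    snp_effects = dash(drugs$snp_effects),
    snp_adverse = dash(drugs$snp_adverse),
    stringsAsFactors = FALSE)
}

empty_drug_cells <- function() {
  data.frame(drug_id = "-", targeted_genes = "-", drug_name = "-",
             prices = "-", snp_effects = "-", snp_adverse = "-",
             stringsAsFactors = FALSE)
}

#' Write the summary and detailed reports
#'
#' Writes \code{summary.tsv} (7 columns) and \code{detailed.tsv}
#' (13 columns), UTF-8, tab-delimited with a header line, importable into a
#' spreadsheet by specifying tab as the delimiter. Embedded tabs and
#' newlines in free text are replaced by single spaces; empty cells are
#' rendered as \code{"-"}. Rows are ordered by input panel order, then trial
#' id, then drug id.
#'
#' @param reports list of \code{gene_report} objects, in panel order.
#' @param out_dir output directory (created if absent).
#' @return named character vector with the two file paths, invisibly.
#' @export
write_reports <- function(reports, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  order_rows <- function(df, cols) {
    if (nrow(df) == 0) return(df)
    df[do.call(order, df[cols]), , drop = FALSE]
  }
  summaries <- lapply(reports, function(r)
    order_rows(r$summary, c("trial_id")))
  details <- lapply(reports, function(r)
    order_rows(r$detail, c("trial_id", "drug_id")))
  summary <- do.call(rbind, c(summaries, list(
    stats::setNames(data.frame(matrix(character(0), ncol = 7),
                               stringsAsFactors = FALSE), SUMMARY_HEADER))))
  detail <- do.call(rbind, c(details, list(
    stats::setNames(data.frame(matrix(character(0), ncol = 13),
                               stringsAsFactors = FALSE), DETAIL_HEADER))))
  write_tsv <- function(df, file) {
    df[] <- lapply(df, sanitize_cell)
    con <- file(file, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(paste(names(df), collapse = "\t"), con)
    if (nrow(df) > 0) {
      writeLines(do.call(paste, c(unname(df), sep = "\t")), con)
    }
  }
  summary_path <- file.path(out_dir, "summary.tsv")
  detail_path <- file.path(out_dir, "detailed.tsv")
  write_tsv(summary, summary_path)
  write_tsv(detail, detail_path)
  invisible(c(summary = summary_path, detailed = detail_path))
}

#' @export
print.gene_report <- function(x, ...) {
  cat("Gene report for", x$gene, "-", nrow(x$summary), "summary row(s),",
      nrow(x$detail), "detail row(s),", nrow(x$drugs), "drug(s)",
      if (x$expanded) "(via interaction-network expansion)" else "", "\n")
  invisible(x)
}
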