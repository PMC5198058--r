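# Run configuration and the end-to-end pipeline driver.

#' Build and validate a run configuration
#'
#' @param genes gene panel: a character vector, or a single string with
#'   whitespace-separated symbols (may span lines). Symbols are upper-cased
#'   and deduplicated preserving first occurrence.
#' @param conditions cancer-type labels restricting the trials, as a
#'   character vector or one comma-separated string; may be empty. Each
#'   label must be a neoplasm vocabulary member (checked at screening time).
#' @param gene_level non-negative integer: maximum number of upstream
#'   interaction levels to expand when a gene has no direct drug match
#'   (0 = no expansion; default 1).
#' @param zip_code origin zip code for proximity filtering ("" = none).
#' @param countries country names restricting trial facilities; empty means
#'   no country filter.
#' @param max_distance maximum facility distance from \code{zip_code};
#'   0 disables proximity filtering. When positive, a zip code is required
#'   and the countries must include the United States (proximity checking
#'   is US-only).
#' @param unit \code{"miles"} or \code{"km"}.
#' @return a validated \code{run_config} list.
#' @examples
#' run_config("brca1 BRCA2\nTP53")
#' @export
run_config <- function(genes, conditions = character(0), gene_level = 1,
                       zip_code = "", countries = character(0),
                       max_distance = 0, unit = c("miles", "km")) {
  unit <- match.arg(unit)
  genes <- normalize_genes(unlist(strsplit(paste(genes, collapse = " "),
                                           "\\s+")))
  genes <- genes[!duplicated(genes)]
  if (length(genes) == 0) {
    stop("parameter 'genes': the gene panel is empty", call. = FALSE)
  }
  conditions <- trimws(unlist(strsplit(paste(conditions, collapse = ","),
                                       ",", fixed = TRUE)))
  conditions <- conditions[nzchar(conditions)]
  if (!is.numeric(gene_level) || length(gene_level) != 1 ||
      is.na(gene_level) || gene_level < 0) {
    stop("parameter 'gene_level': must be a non-negative integer",
         call. = FALSE)
  }
  if (!is.numeric(max_distance) || length(max_distance) != 1 ||
      is.na(max_distance) || max_distance < 0) {
    stop("parameter 'max_distance': must be non-negative", call. = FALSE)
  }
  zip_code <- if (nzchar(trimws(zip_code))) normalize_zip(zip_code) else ""
  if (max_distance > 0) {
    if (!nzchar(zip_code)) {
      stop("parameter 'zip_code': required when max_distance > 0",
           call. = FALSE)
    }
    if (!("united states" %in% tolower(countries))) {
      stop("parameter 'countries': must include the United States when ",
           "max_distance > 0 (proximity checking is US-only)",
           call. = FALSE)
    }
  }
  structure(list(genes = genes, conditions = conditions,
                 gene_level = as.integer(gene_level), zip_code = zip_code,
                 countries = trimws(countries),
                 max_distance = as.numeric(max_distance), unit = unit),
            class = "run_config")
}

#' Read a gene-panel file
#'
#' One HGNC symbol per whitespace-separated token; symbols may span
#' multiple lines.
#'
#' @param file path to the panel file.
#' @return character vector of upper-cased, deduplicated symbols.
#' @export
read_gene_panel <- function(file) {
  if (!file.exists(file)) stop("gene panel file not found: ", file,
                               call. = FALSE)
  genes <- normalize_genes(unlist(strsplit(readLines(file, warn = FALSE),
                                           "\\s+")))
  genes <- genes[!duplicated(genes)]
  if (length(genes) == 0) stop("gene panel file is empty: ", file,
                               call. = FALSE)
  genes
}

#' Run the full screening and matching pipeline
#'
#' For each panel gene: screen every trial record with the four predicates,
#' match the gene to cancer drugs in the catalog (expanding over the
#' interaction network when no direct drug exists and the gene level is
#' positive), apply facility proximity filtering, and integrate everything
#' into the summary and detailed reports. A run log records per-gene
#' accepted/rejected counts with reasons. All inputs are parsed before any
#' output is written, so a fatal input error aborts the run without leaving
#' partial reports.
#'
#' @param config a \code{run_config}.
#' @param paths named list/vector of input paths: \code{trials} (XML file
#'   or directory), \code{catalog} (TSV), \code{mesh} (tree file),
#'   \code{sif} (one or more SIF files; optional when
#'   \code{gene_level = 0}), \code{zips} (CSV; optional when
#'   \code{max_distance = 0}).
#' @param out_dir output directory for \code{summary.tsv},
#'   \code{detailed.tsv} and \code{run.log}.
#' @return invisibly, a list with \code{reports} (per-gene
#'   \code{gene_report}s), \code{decisions} (named list of per-gene
#'   screening data.frames) and \code{files}.
#' @export
run_pipeline <- function(config, paths, out_dir) {
  stopifnot(inherits(config, "run_config"))
  need <- c("trials", "catalog", "mesh")
  missing_in <- setdiff(need, names(paths))
  if (length(missing_in) > 0) {
    stop("missing input path(s): ", paste(missing_in, collapse = ", "),
         call. = FALSE)
  }
  vocab <- neoplasm_vocabulary(parse_mesh_tree(paths$mesh))
  check_user_conditions(config$conditions, vocab)
  catalog <- index_catalog(parse_drug_catalog(paths$catalog), vocab)
  corpus <- parse_trials(paths$trials)
  graph <- NULL
  if (config$gene_level > 0) {
    if (is.null(paths$sif)) {
      stop("SIF input required when gene_level > 0", call. = FALSE)
    }
    graph <- parse_sif(unlist(paths$sif))
  }
  zip_table <- NULL
  if (config$max_distance > 0) {
    if (is.null(paths$zips)) {
      stop("zip table required when max_distance > 0", call. = FALSE)
    }
    zip_table <- read_zip_table(paths$zips)
    if (is.null(zip_point(config$zip_code, zip_table))) {
      stop("origin zip code not found in the coordinate table: ",
           config$zip_code, call. = FALSE)
    }
  }
  reports <- list()
  decisions <- list()
  log_lines <- c(sprintf("panel: %s", paste(config$genes, collapse = " ")),
                 sprintf("trials parsed: %d", length(corpus)))
  for (gene in config$genes) {
    dec <- screen_corpus(corpus, gene, vocab, config$countries,
                         config$conditions)
    decisions[[gene]] <- dec
    accepted <- corpus[dec$accepted]
    rej <- dec[!dec$accepted, , drop = FALSE]
    reason_tab <- sort(table(unlist(rej$reasons)), decreasing = TRUE)
    log_lines <- c(log_lines, sprintf(
      "%s: %d accepted, %d rejected%s", gene, sum(dec$accepted),
      sum(!dec$accepted),
      if (length(reason_tab) > 0) {
        paste0(" (", paste(sprintf("%s=%d", names(reason_tab),
                                   as.integer(reason_tab)),
                           collapse = ", "), ")")
      } else ""))
    reports[[gene]] <- build_gene_report(gene, accepted, catalog, graph,
                                         config, zip_table)
  }
  files <- write_reports(reports, out_dir)
  log_path <- file.path(out_dir, "run.log")
  writeLines(log_lines, log_path)
  message(paste(log_lines, collapse = "\n"))
  invisible(list(reports = reports, decisions = decisions,
                 files = c(files, log = log_path)))
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration\n",
      "  genes:        ", paste(x$genes, collapse = " "), "\n",
      "  conditions:   ", if (length(x$conditions)) paste(x$conditions, collapse = ", ") else "(none)", "\n",
      "  gene level:   ", x$gene_level, "\n",
      "  countries:    ", if (length(x$countries)) paste(x$countries, collapse = ", ") else "(none)", "\n",
      "  proximity:    ", if (x$max_distance > 0)
        sprintf("within %g %s of %s", x$max_distance, x$unit, x$zip_code)
      else "off", "\n", sep = "")
  invisible(x)
}
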