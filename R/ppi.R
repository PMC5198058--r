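# Typed protein-protein interaction graphs (SIF files) and bounded
# upstream expansion of the drug search.

#' The twelve recognized interaction-type labels
#'
#' The closed set of interaction types annotated in the Pathway Commons
#' binary SIF exports of Reactome and NCI PID.
#'
#' @return character vector of the 12 labels.
#' @export
interaction_types <- function() {
  c("catalysis-precedes", "chemical-affects", "consumption-controlled-by",
    "controls-expression-of", "controls-phosphorylation-of",
    "controls-production-of", "controls-state-change-of",
    "controls-transport-of", "controls-transport-of-chemical",
    "in-complex-with", "reacts-with", "used-to-produce")
}

# Labels under which the SOURCE counts as upstream of the TARGET.
UPSTREAM_FORWARD <- c("controls-expression-of", "controls-state-change-of",
                      "controls-phosphorylation-of", "controls-transport-of",
                      "controls-production-of", "chemical-affects",
                      "catalysis-precedes")
# "A consumption-controlled-by B" means B controls A: TARGET is upstream.
UPSTREAM_REVERSED <- "consumption-controlled-by"
# Complex membership is treated as undirected partnership.
UPSTREAM_UNDIRECTED <- "in-complex-with"

#' Parse and merge SIF interaction files
#'
#' Each file is three-column tab-separated text: source gene, interaction
#' type, target gene. Files are merged into one deduplicated edge set keyed
#' by the (source, type, target) triple; gene symbols are upper-cased.
#' Lines whose interaction type is outside the twelve recognized labels are
#' skipped with a warning and counted in the \code{"n_skipped"} attribute.
#'
#' @param files character vector of SIF file paths.
#' @return an object of class \code{interaction_graph}: a data.frame with
#'   columns \code{source}, \code{type}, \code{target}, \code{file}
#'   (provenance tag of the first file contributing the edge).
#' @export
parse_sif <- function(files) {
  stopifnot(length(files) >= 1)
  src <- typ <- tgt <- prov <- character(0)
  n_skipped <- 0L
  for (f in files) {
    if (!file.exists(f)) stop("SIF file not found: ", f, call. = FALSE)
    lines <- readLines(f, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    for (ln in lines) {
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(parts) < 3) { n_skipped <- n_skipped + 1L; next }
      ty <- tolower(trimws(parts[2]))
      if (!(ty %in% interaction_types())) { n_skipped <- n_skipped + 1L; next }
      src <- c(src, toupper(trimws(parts[1])))
      typ <- c(typ, ty)
      tgt <- c(tgt, toupper(trimws(parts[3])))
      prov <- c(prov, basename(f))
    }
  }
  if (n_skipped > 0L) {
    warning(n_skipped, " SIF line(s) skipped (malformed or unknown ",
            "interaction type)", call. = FALSE)
  }
  if (length(src) == 0L) {
    stop("no parseable interaction edges in: ",
         paste(files, collapse = ", "), call. = FALSE)
  }
  key <- paste(src, typ, tgt, sep = "\r")
  keep <- !duplicated(key)
  edges <- data.frame(source = src[keep], type = typ[keep],
                      target = tgt[keep], file = prov[keep],
                      stringsAsFactors = FALSE)
  attr(edges, "n_skipped") <- n_skipped
  class(edges) <- c("interaction_graph", class(edges))
  edges
}

#' Upstream regulators and complex partners of a gene
#'
#' Returns the genes that either control the queried gene through a directed
#' control-type edge (expression, state change, phosphorylation, transport,
#' production, chemical effect, catalysis precedence, or a reversed
#' consumption-control edge) or share an \code{in-complex-with} edge with it
#' in either direction. Downstream targets of the queried gene do not
#' qualify; the gene itself is never returned.
#'
#' @param gene an HGNC gene symbol.
#' @param graph an \code{interaction_graph} from [parse_sif()].
#' @return sorted character vector of gene symbols (possibly empty).
#' @export
upstream_interactors <- function(gene, graph) {
  gene <- normalize_genes(gene)
  up <- c(
    graph$source[graph$target == gene & graph$type %in% UPSTREAM_FORWARD],
    graph$target[graph$source == gene & graph$type %in% UPSTREAM_REVERSED],
    graph$source[graph$target == gene & graph$type %in% UPSTREAM_UNDIRECTED],
    graph$target[graph$source == gene & graph$type %in% UPSTREAM_UNDIRECTED]
  )
  sort(unique(setdiff(up, gene)))
}

#' Expand the drug search over the interaction network
#'
#' When the queried gene has at least one direct cancer-drug hit, the result
#' holds only level 0 and no expansion occurs. Otherwise the search walks
#' upstream breadth-first: level k holds the genes first reached after k
#' upstream steps, each mapped to its direct drug hits in the catalog.
#' Visited genes are never re-expanded, so each gene appears at exactly one
#' level (the first at which it is reached). \code{max_level = 0} disables
#' expansion entirely. Frontier and output order is lexicographic by gene
#' symbol for reproducibility. Hits are accumulated at every level up to
#' \code{max_level} (the walk does not stop at the first level with a hit).
#'
#' @param gene queried HGNC gene symbol.
#' @param max_level non-negative integer; maximum number of upstream steps.
#' @param graph an \code{interaction_graph}.
#' @param catalog an indexed \code{drug_catalog}.
#' @return an object of class \code{expansion_result}: a list with
#'   \code{gene}, \code{levels} (named list \code{"0"}, \code{"1"}, ...;
#'   each level a named list gene -> data.frame of drug records) and
#'   \code{visited}.
#' @export
expand_gene_search <- function(gene, max_level, graph, catalog) {
  stopifnot(is.numeric(max_level), max_level >= 0)
  max_level <- as.integer(max_level)
  gene <- normalize_genes(gene)
  direct <- drugs_targeting(gene, catalog)
  levels <- list()
  levels[["0"]] <- stats::setNames(list(direct), gene)
  visited <- gene
  if (nrow(direct) == 0 && max_level > 0) {
    frontier <- gene
    for (k in seq_len(max_level)) {
      nxt <- sort(unique(unlist(lapply(frontier, upstream_interactors,
                                       graph = graph))))
      nxt <- setdiff(nxt, visited)
      if (length(nxt) == 0) break
      levels[[as.character(k)]] <-
        stats::setNames(lapply(nxt, drugs_targeting, catalog = catalog), nxt)
      visited <- c(visited, nxt)
      frontier <- nxt
    }
  }
  structure(list(gene = gene, levels = levels, visited = visited),
            class = "expansion_result")
}

#' Flatten an expansion result to its distinct drug records
#'
#' Collects the drug hits of every level and interactor, deduplicated by
#' drug id and sorted by id. Each row carries a \code{via_genes} column:
#' the \code{";"}-joined interactor genes (or the queried gene itself at
#' level 0) through which that drug was reached.
#'
#' @param expansion an \code{expansion_result}.
#' @return data.frame of distinct drug records plus \code{via_genes}.
#' @export
expansion_drugs <- function(expansion) {
  stopifnot(inherits(expansion, "expansion_result"))
  via <- list()
  rows <- list()
  for (lev in expansion$levels) {
    for (g in names(lev)) {
      hits <- lev[[g]]
      if (is.null(hits) || nrow(hits) == 0) next
      for (i in seq_len(nrow(hits))) {
        id <- hits$drug_id[i]
        via[[id]] <- unique(c(via[[id]], g))
        rows[[id]] <- hits[i, , drop = FALSE]
      }
    }
  }
  ids <- sort(names(rows))
  if (length(ids) == 0) {
    out <- data.frame(drug_id = character(0), stringsAsFactors = FALSE)
    out$via_genes <- character(0)
    return(out)
  }
  out <- do.call(rbind, rows[ids])
  out$via_genes <- vapply(ids, function(id)
    paste(sort(via[[id]]), collapse = "; "), character(1))
  rownames(out) <- NULL
  out
}

#' @export
print.expansion_result <- function(x, ...) {
  nlev <- length(x$levels) - 1L
  nd <- nrow(expansion_drugs(x))
  cat("Expansion for", x$gene, "-", nlev, "level(s) walked,",
      length(x$visited) - 1L, "interactor gene(s),", nd,
      "distinct drug(s)\n")
  invisible(x)
}
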