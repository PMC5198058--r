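# MeSH tree parsing and the neoplasm (C04 subtree) vocabulary.

#' Parse a MeSH tree file
#'
#' Reads a two-column, semicolon-delimited MeSH tree file
#' (\code{heading;tree_number}, one pair per line; lines starting with
#' \code{#} are comments). Tree numbers are dot-separated codes encoding the
#' position of a heading in the MeSH hierarchy, e.g. \code{"C04.182"} for
#' "Cysts"; prefix relationships encode ancestry.
#'
#' Malformed lines (missing field, empty heading or tree number) are skipped
#' with a warning; the number skipped is recorded in the \code{"n_skipped"}
#' attribute of the result.
#'
#' @param file path to the MeSH tree file.
#' @return a data.frame with columns \code{heading} and \code{tree_number},
#'   one row per parsed line, input order preserved.
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines(c("Neoplasms;C04", "Cysts;C04.182"), f)
#' parse_mesh_tree(f)
#' @export
parse_mesh_tree <- function(file) {
  if (!file.exists(file)) {
    stop("MeSH tree file not found: ", file, call. = FALSE)
  }
  lines <- readLines(file, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  headings <- character(0)
  trees <- character(0)
  n_skipped <- 0L
  for (ln in lines) {
    parts <- trimws(strsplit(ln, ";", fixed = TRUE)[[1]])
    if (length(parts) < 2L || !nzchar(parts[1]) || !nzchar(parts[2])) {
      n_skipped <- n_skipped + 1L
      next
    }
    headings <- c(headings, parts[1])
    trees <- c(trees, parts[2])
  }
  if (n_skipped > 0L) {
    warning(n_skipped, " malformed MeSH line(s) skipped", call. = FALSE)
  }
  if (length(headings) == 0L) {
    stop("no parseable MeSH entries in ", file, call. = FALSE)
  }
  out <- data.frame(heading = headings, tree_number = trees,
                    stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Extract the neoplasm vocabulary from parsed MeSH entries
#'
#' Keeps the headings of entries whose tree number is \code{"C04"} or starts
#' with \code{"C04."} — the neoplasms subtree of MeSH. A heading listed under
#' both a C04 and a non-C04 tree number is included. Headings are
#' deduplicated case-insensitively (one heading may carry several tree
#' numbers).
#'
#' @param entries data.frame from [parse_mesh_tree()].
#' @return an object of class \code{neoplasm_vocab}: a list with
#'   \code{headings} (sorted canonical headings) and precomputed matching
#'   variants used by [match_neoplasm_terms()].
#' @export
neoplasm_vocabulary <- function(entries) {
  stopifnot(is.data.frame(entries),
            all(c("heading", "tree_number") %in% names(entries)))
  is_c04 <- entries$tree_number == "C04" |
    startsWith(entries$tree_number, "C04.")
  headings <- trimws(entries$heading[is_c04])
  headings <- headings[nzchar(headings)]
  headings <- headings[!duplicated(tolower(headings))]
  headings <- headings[order(tolower(headings))]
  if (length(headings) == 0L) {
    warning("neoplasm vocabulary is empty", call. = FALSE)
  }
  variants <- lapply(headings, heading_variants)
  names(variants) <- headings
  structure(list(headings = headings, variants = variants),
            class = "neoplasm_vocab")
}

#' @export
print.neoplasm_vocab <- function(x, ...) {
  cat("Neoplasm MeSH vocabulary:", length(x$headings), "headings\n")
  if (length(x$headings) > 0) {
    show <- utils::head(x$headings, 6)
    cat("  ", paste(show, collapse = "; "),
        if (length(x$headings) > 6) "; ..." else "", "\n", sep = "")
  }
  invisible(x)
}

# Matching variants for one MeSH heading.
#
# MeSH presents many headings in inverted form ("Carcinoma, Non-Small-Cell
# Lung"); free text uses the natural order, often without the trailing
# qualifier segments ("chronic lymphocytic leukemia" for "Leukemia,
# Lymphocytic, Chronic, B-Cell"). Variants generated: the heading itself,
# plus, for each k = n..1, the first k comma segments reversed and joined
# ("B-Cell Chronic Lymphocytic Leukemia", "Chronic Lymphocytic Leukemia",
# ..., "Leukemia"). Variants shorter than 4 characters after normalization
# are discarded to avoid degenerate matches.
heading_variants <- function(heading) {
  segs <- trimws(strsplit(heading, ",", fixed = TRUE)[[1]])
  segs <- segs[nzchar(segs)]
  vars <- normalize_text(heading)
  if (length(segs) > 1L) {
    for (k in seq(length(segs), 1L)) {
      vars <- c(vars, normalize_text(paste(rev(segs[seq_len(k)]),
                                           collapse = " ")))
    }
  }
  vars <- unique(vars)
  vars[nchar(vars) >= 4L]
}

#' Find neoplasm vocabulary headings occurring in free text
#'
#' A heading matches when any of its variants (the heading, or its comma
#' segments reordered to natural word order, optionally dropping trailing
#' qualifier segments) is contained in the text as a whole phrase, after
#' case-folding and punctuation normalization on both sides.
#'
#' @param text a character string (free text).
#' @param vocab a \code{neoplasm_vocab} from [neoplasm_vocabulary()].
#' @return character vector of matched canonical headings, in vocabulary
#'   (alphabetical) order; empty when nothing matches.
#' @export
match_neoplasm_terms <- function(text, vocab) {
  stopifnot(inherits(vocab, "neoplasm_vocab"))
  if (length(text) == 0) return(character(0))
  text <- paste(text, collapse = " ")
  norm <- normalize_text(text)
  if (!nzchar(norm) || length(vocab$headings) == 0L) return(character(0))
  hit <- vapply(vocab$variants, function(vars) {
    any(vapply(vars, phrase_in_text, logical(1), text = norm))
  }, logical(1))
  vocab$headings[hit]
}

#' Write the vocabulary as one heading per line (audit dump)
#'
#' @param vocab a \code{neoplasm_vocab}.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_vocabulary <- function(vocab, file) {
  stopifnot(inherits(vocab, "neoplasm_vocab"))
  writeLines(vocab$headings, file)
  invisible(file)
}
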