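# Shared helpers: text normalization, whole-phrase matching, field splitting.

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

#' Normalize free text for vocabulary matching
#'
#' Lower-cases, maps separator punctuation (commas, semicolons, colons,
#' slashes, parentheses, hyphens) to spaces and squeezes whitespace, so that
#' phrase containment is insensitive to hyphenation and list punctuation.
#'
#' @param x character vector.
#' @return character vector of the same length.
#' @keywords internal
normalize_text <- function(x) {
  x <- tolower(as.character(x))
  x <- gsub("[,;:/()\\[\\]–—-]", " ", x, perl = TRUE)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

# Whole-word containment of a normalized phrase in normalized text.
phrase_in_text <- function(phrase, text) {
  if (!nzchar(phrase) || !nzchar(text)) return(FALSE)
  pattern <- paste0("\\b", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", phrase), "\\b")
  grepl(pattern, text, perl = TRUE)
}

# Split a ";"-joined multi-valued cell into trimmed non-empty tokens.
split_multi <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(character(0))
  parts <- trimws(strsplit(x, ";", fixed = TRUE)[[1]])
  parts[nzchar(parts)]
}

# Upper-case and trim gene symbols; drop empties.
normalize_genes <- function(x) {
  x <- toupper(trimws(x))
  x[nzchar(x)]
}

# Collapse embedded tabs/newlines so a value is safe inside a TSV cell.
sanitize_cell <- function(x) {
  x <- gsub("[\t\r\n]+", " ", as.character(x))
  x[!nzchar(trimws(x)) | is.na(x)] <- "-"
  x
}
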