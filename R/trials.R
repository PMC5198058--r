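# Clinical-trial record parsing and the four screening predicates.

REASON_CODES <- c("NO_GENE_MENTION", "NOT_CANCER", "NO_DRUG",
                  "NOT_RECRUITING", "NO_LOCATION_IN_COUNTRY")

#' Parse a trial-corpus XML file
#'
#' Reads registry records from the trial XML dialect: root \code{<trials>},
#' one \code{<trial>} per record with children \code{<id>}, \code{<title>},
#' \code{<status>}, \code{<phase>}, repeated \code{<condition>} and
#' \code{<mesh_term>}, \code{<intervention type="...">name</intervention>},
#' an optional free-text \code{<summary>}, and \code{<location
#' recruiting="true|false">} elements holding \code{<facility>},
#' \code{<city>}, \code{<state>}, \code{<zip>}, \code{<country>},
#' \code{<contact>}. A location without a \code{recruiting} attribute
#' inherits the trial-level recruiting status.
#'
#' @param path a trial XML file, or a directory whose \code{*.xml} files are
#'   all read.
#' @return a list of trial records (class \code{trial_corpus}); each record
#'   is a list with fields \code{trial_id}, \code{title}, \code{status},
#'   \code{phase}, \code{conditions}, \code{mesh_terms}, \code{summary},
#'   \code{interventions} (data.frame type/name) and \code{locations}
#'   (data.frame facility/city/state/zip/country/contact/recruiting).
#' @export
parse_trials <- function(path) {
  files <- if (dir.exists(path)) {
    list.files(path, pattern = "\\.xml$", full.names = TRUE)
  } else path
  if (length(files) == 0 || !all(file.exists(files))) {
    stop("no trial XML file(s) found at: ", path, call. = FALSE)
  }
  records <- list()
  for (f in files) {
    doc <- tryCatch(xml2::read_xml(f),
                    error = function(e) stop("malformed trial XML in ", f,
                                             ": ", conditionMessage(e),
                                             call. = FALSE))
    for (node in xml2::xml_find_all(doc, "//trial")) {
      records[[length(records) + 1L]] <- parse_trial_node(node)
    }
  }
  if (length(records) == 0) {
    stop("zero trial records parsed from: ", path, call. = FALSE)
  }
  ids <- vapply(records, `[[`, character(1), "trial_id")
  if (anyDuplicated(ids)) {
    stop("duplicate trial id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  structure(records, class = "trial_corpus")
}

xml_text1 <- function(node, xpath) {
  n <- xml2::xml_find_first(node, xpath)
  if (inherits(n, "xml_missing")) "" else trimws(xml2::xml_text(n))
}

parse_trial_node <- function(node) {
  status <- xml_text1(node, "./status")
  ivs <- xml2::xml_find_all(node, "./intervention")
  interventions <- data.frame(
    type = trimws(xml2::xml_attr(ivs, "type")),
    name = trimws(xml2::xml_text(ivs)),
    stringsAsFactors = FALSE
  )
  locs <- xml2::xml_find_all(node, "./location")
  rec_attr <- xml2::xml_attr(locs, "recruiting")
  rec_default <- identical(tolower(status), "recruiting")
  locations <- data.frame(
    facility = vapply(locs, xml_text1, character(1), "./facility"),
    city = vapply(locs, xml_text1, character(1), "./city"),
    state = vapply(locs, xml_text1, character(1), "./state"),
    zip = vapply(locs, xml_text1, character(1), "./zip"),
    country = vapply(locs, xml_text1, character(1), "./country"),
    contact = vapply(locs, xml_text1, character(1), "./contact"),
    recruiting = ifelse(is.na(rec_attr), rec_default,
                        tolower(rec_attr) == "true"),
    stringsAsFactors = FALSE
  )
  list(
    trial_id = xml_text1(node, "./id"),
    title = xml_text1(node, "./title"),
    status = status,
    phase = xml_text1(node, "./phase"),
    conditions = trimws(xml2::xml_text(xml2::xml_find_all(node, "./condition"))),
    mesh_terms = trimws(xml2::xml_text(xml2::xml_find_all(node, "./mesh_term"))),
    summary = xml_text1(node, "./summary"),
    interventions = interventions,
    locations = locations
  )
}

# All textual content of a record, for unrestricted keyword search.
trial_full_text <- function(trial) {
  paste(c(trial$trial_id, trial$title, trial$conditions, trial$mesh_terms,
          trial$summary, trial$interventions$name, trial$locations$facility,
          trial$locations$contact), collapse = " ")
}

#' Does a trial mention a gene symbol?
#'
#' Criterion 1: the queried gene symbol must occur somewhere in the record,
#' in any field, as a whole word (case-insensitive). Substring hits inside
#' longer words do not count, so querying ATM never matches "TREATMENT".
#'
#' @param trial a trial record.
#' @param gene an HGNC gene symbol.
#' @return logical scalar.
#' @export
mentions_gene <- function(trial, gene) {
  gene <- normalize_genes(gene)
  grepl(paste0("\\b", gene, "\\b"), toupper(trial_full_text(trial)),
        perl = TRUE)
}

#' Is a trial a cancer trial?
#'
#' Criterion 2: the disease-condition subsection (tagged MeSH terms or
#' condition strings) must contain at least one neoplasm vocabulary heading.
#'
#' @param trial a trial record.
#' @param vocab a \code{neoplasm_vocab}.
#' @return logical scalar.
#' @export
is_cancer_trial <- function(trial, vocab) {
  length(match_neoplasm_terms(c(trial$mesh_terms, trial$conditions),
                              vocab)) > 0
}

#' Does a trial have a drug intervention?
#'
#' Criterion 3: at least one intervention of type \code{"drug"}
#' (case-insensitive) with a non-empty compound name. Device, procedure and
#' dietary-supplement arms do not qualify.
#'
#' @param trial a trial record.
#' @return logical scalar.
#' @export
has_drug_intervention <- function(trial) {
  iv <- trial$interventions
  nrow(iv) > 0 && any(tolower(iv$type) == "drug" & nzchar(iv$name))
}

#' Is a trial actively recruiting (optionally in given countries)?
#'
#' Criterion 4: the overall status must be exactly "Recruiting" (after
#' trimming and case-folding; "Not yet recruiting" and "Active, not
#' recruiting" fail), and, when countries are specified, at least one
#' actively recruiting facility must lie in one of them.
#'
#' @param trial a trial record.
#' @param countries character vector of country names (empty = no country
#'   restriction).
#' @return logical scalar.
#' @export
is_recruiting_in <- function(trial, countries = character(0)) {
  if (!identical(tolower(trimws(trial$status)), "recruiting")) return(FALSE)
  if (length(countries) == 0) return(TRUE)
  locs <- trial$locations
  any(locs$recruiting & tolower(locs$country) %in% tolower(countries))
}

#' Screen one trial against the four predicates
#'
#' Evaluates all predicates independently (no short-circuit) and records a
#' reason code for each failure: \code{NO_GENE_MENTION}, \code{NOT_CANCER},
#' \code{NO_DRUG}, \code{NOT_RECRUITING} (overall status not "Recruiting"),
#' \code{NO_LOCATION_IN_COUNTRY} (country restriction given but no
#' recruiting facility in those countries). When user conditions are
#' supplied, the trial's condition subsection must additionally contain one
#' of them (failures are reported as \code{NOT_CANCER}: the trial studies
#' the wrong cancer type).
#'
#' @param trial a trial record.
#' @param gene queried HGNC gene symbol.
#' @param vocab a \code{neoplasm_vocab}.
#' @param countries character vector of country names (may be empty).
#' @param conditions user-specified cancer-type labels (may be empty); each
#'   must itself be a member of the neoplasm vocabulary.
#' @return an object of class \code{screen_decision}: list with
#'   \code{trial_id}, \code{accepted}, \code{reasons}.
#' @export
screen_trial <- function(trial, gene, vocab, countries = character(0),
                         conditions = character(0)) {
  conditions <- check_user_conditions(conditions, vocab)
  reasons <- character(0)
  if (!mentions_gene(trial, gene)) reasons <- c(reasons, "NO_GENE_MENTION")
  cancer_ok <- is_cancer_trial(trial, vocab)
  if (cancer_ok && length(conditions) > 0) {
    cond_text <- normalize_text(paste(c(trial$mesh_terms, trial$conditions),
                                      collapse = " "))
    cancer_ok <- any(vapply(normalize_text(conditions), phrase_in_text,
                            logical(1), text = cond_text))
  }
  if (!cancer_ok) reasons <- c(reasons, "NOT_CANCER")
  if (!has_drug_intervention(trial)) reasons <- c(reasons, "NO_DRUG")
  if (!identical(tolower(trimws(trial$status)), "recruiting")) {
    reasons <- c(reasons, "NOT_RECRUITING")
  }
  if (length(countries) > 0) {
    locs <- trial$locations
    if (!any(locs$recruiting & tolower(locs$country) %in% tolower(countries))) {
      reasons <- c(reasons, "NO_LOCATION_IN_COUNTRY")
    }
  }
  reasons <- unique(reasons)
  structure(list(trial_id = trial$trial_id,
                 accepted = length(reasons) == 0,
                 reasons = reasons),
            class = "screen_decision")
}

# User conditions must be neoplasm vocabulary members (fatal otherwise).
check_user_conditions <- function(conditions, vocab) {
  conditions <- trimws(conditions)
  conditions <- conditions[nzchar(conditions)]
  if (length(conditions) == 0) return(character(0))
  ok <- vapply(conditions, function(cond)
    length(match_neoplasm_terms(cond, vocab)) > 0, logical(1))
  if (!all(ok)) {
    stop("user condition(s) not in the neoplasm vocabulary: ",
         paste(conditions[!ok], collapse = ", "), call. = FALSE)
  }
  conditions
}

#' Screen a whole corpus for one gene
#'
#' @param corpus a \code{trial_corpus} from [parse_trials()].
#' @inheritParams screen_trial
#' @return a data.frame with columns \code{trial_id}, \code{accepted}, and
#'   list-column \code{reasons}; one row per trial, corpus order.
#' @export
screen_corpus <- function(corpus, gene, vocab, countries = character(0),
                          conditions = character(0)) {
  decisions <- lapply(corpus, screen_trial, gene = gene, vocab = vocab,
                      countries = countries, conditions = conditions)
  data.frame(
    trial_id = vapply(decisions, `[[`, character(1), "trial_id"),
    accepted = vapply(decisions, `[[`, logical(1), "accepted"),
    reasons = I(lapply(decisions, `[[`, "reasons")),
    stringsAsFactors = FALSE
  )
}

#' @export
print.screen_decision <- function(x, ...) {
  cat(x$trial_id, if (x$accepted) "ACCEPTED"
      else paste("REJECTED:", paste(x$reasons, collapse = ", ")), "\n")
  invisible(x)
}

#' @export
print.trial_corpus <- function(x, ...) {
  cat("Trial corpus:", length(x), "record(s)\n")
  invisible(x)
}
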