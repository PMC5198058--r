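# Shared in-code fixtures for the test suite.

default_vocab <- function() {
  neoplasm_vocabulary(default_mesh_entries())
}

# Memoized demo workspace: all six synthetic input files, built once.
demo_paths <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- file.path(tempdir(), "oncoscreen-demo")
      cache <<- make_demo_workspace(d, seed = 42L)
    }
    cache
  }
})

indexed_catalog <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- index_catalog(parse_drug_catalog(demo_paths()[["catalog"]]),
                              default_vocab())
    }
    cache
  }
})

demo_graph <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- parse_sif(demo_paths()[["sif"]])
    cache
  }
})

# Construct a trial record directly (bypassing XML) for predicate tests.
make_trial <- function(id = "NCT00000001",
                       title = "A study",
                       status = "Recruiting",
                       phase = "Phase 2",
                       conditions = "Breast Neoplasms",
                       mesh_terms = "Breast Neoplasms",
                       summary = "",
                       interventions = data.frame(
                         type = "drug", name = "Agent-001",
                         stringsAsFactors = FALSE),
                       locations = data.frame(
                         facility = "Site A", city = "Allentown",
                         state = "PA", zip = "18102",
                         country = "United States", contact = "c@x.org",
                         recruiting = TRUE, stringsAsFactors = FALSE)) {
  list(trial_id = id, title = title, status = status, phase = phase,
       conditions = conditions, mesh_terms = mesh_terms, summary = summary,
       interventions = interventions, locations = locations)
}

# Independent re-derivation of the upstream rule for oracle tests:
# plain loops over the edge rows, no shared code with the implementation.
oracle_upstream <- function(gene, edges) {
  fwd <- c("controls-expression-of", "controls-state-change-of",
           "controls-phosphorylation-of", "controls-transport-of",
           "controls-production-of", "chemical-affects",
           "catalysis-precedes")
  out <- character(0)
  for (i in seq_len(nrow(edges))) {
    s <- edges$source[i]; ty <- edges$type[i]; t <- edges$target[i]
    if (ty %in% fwd && t == gene) out <- c(out, s)
    if (ty == "consumption-controlled-by" && s == gene) out <- c(out, t)
    if (ty == "in-complex-with" && t == gene) out <- c(out, s)
    if (ty == "in-complex-with" && s == gene) out <- c(out, t)
  }
  sort(unique(setdiff(out, gene)))
}

# Brute-force level-bounded upstream walk returning the flattened set of
# drug ids, for comparison with expand_gene_search()/expansion_drugs().
oracle_expansion_ids <- function(gene, max_level, edges, catalog) {
  direct <- drugs_targeting(gene, catalog)$drug_id
  if (length(direct) > 0 || max_level == 0) return(sort(direct))
  visited <- gene
  frontier <- gene
  ids <- character(0)
  lev <- 0
  while (lev < max_level && length(frontier) > 0) {
    lev <- lev + 1
    nxt <- character(0)
    for (g in frontier) nxt <- c(nxt, oracle_upstream(g, edges))
    nxt <- sort(unique(setdiff(nxt, visited)))
    for (g in nxt) ids <- c(ids, drugs_targeting(g, catalog)$drug_id)
    visited <- c(visited, nxt)
    frontier <- nxt
  }
  sort(unique(ids))
}

# Random small typed edge list for property tests.
random_edges <- function(n_edges, n_genes = 8) {
  genes <- sprintf("G%02d", seq_len(n_genes))
  types <- interaction_types()
  data.frame(source = sample(genes, n_edges, replace = TRUE),
             type = sample(types, n_edges, replace = TRUE),
             target = sample(genes, n_edges, replace = TRUE),
             stringsAsFactors = FALSE)
}
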