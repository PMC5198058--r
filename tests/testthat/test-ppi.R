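write_sif <- function(edges) {
  f <- tempfile(fileext = ".sif")
  make_sif_file(f, edges)
  f
}

test_that("SIF parsing merges files, deduplicates edges and skips unknown types", {
  e1 <- data.frame(source = "CDK2", type = "controls-state-change-of",
                   target = "BRCA1", stringsAsFactors = FALSE)
  e2 <- rbind(e1, data.frame(source = "CDK7", type = "controls-expression-of",
                             target = "BRCA1", stringsAsFactors = FALSE))
  g <- parse_sif(c(write_sif(e1), write_sif(e2)))
  expect_equal(nrow(g), 2L)  # shared edge collapses across files

  f <- tempfile(fileext = ".sif")
  writeLines(c("A\tbinds\tB", "cdk2\tcontrols-state-change-of\tbrca1"), f)
  expect_warning(g2 <- parse_sif(f), "skipped")
  expect_equal(nrow(g2), 1L)
  expect_equal(g2$source, "CDK2")  # symbols upper-cased

  # disjoint files: brute-force union oracle
  gA <- data.frame(source = "A", type = "in-complex-with", target = "B",
                   stringsAsFactors = FALSE)
  gB <- data.frame(source = "C", type = "reacts-with", target = "D",
                   stringsAsFactors = FALSE)
  merged <- parse_sif(c(write_sif(gA), write_sif(gB)))
  expect_equal(nrow(merged), nrow(unique(rbind(gA, gB))))

  bad <- tempfile(fileext = ".sif")
  writeLines("A\tbinds\tB", bad)
  expect_error(suppressWarnings(parse_sif(bad)), "no parseable")
})

test_that("upstream interactors follow the direction rules of each label", {
  g <- demo_graph()
  expect_equal(upstream_interactors("BRCA1", g)[1:5],
               c("AURKA", "AURKB", "CDK2", "CDK7", "CDK9"))
  expect_true(all(c("CDK2", "CDK7", "CDK9") %in%
                    upstream_interactors("BRCA1", g)))
  expect_equal(upstream_interactors("ATM", g),
               c("CDK7", "CDK9", "CHEK1", "CHEK2", "POLE", "POLE2"))
  expect_equal(upstream_interactors("ABSENT", g), character(0))
  # downstream control edges do not qualify: BRCA1 controls ESR1
  expect_false("ESR1" %in% upstream_interactors("BRCA1", g))
  expect_true("BRCA1" %in% upstream_interactors("ESR1", g))
  # non-qualifying labels never contribute
  expect_false("UBE2D1" %in% upstream_interactors("BRCA1", g))
  # reversed label: consumption-controlled-by points downstream-to-upstream
  rg <- parse_sif(write_sif(data.frame(
    source = "GLC", type = "consumption-controlled-by", target = "HK1",
    stringsAsFactors = FALSE)))
  expect_equal(upstream_interactors("GLC", rg), "HK1")
  expect_equal(upstream_interactors("HK1", rg), character(0))
  # in-complex-with is undirected
  cg <- parse_sif(write_sif(data.frame(
    source = "A", type = "in-complex-with", target = "B",
    stringsAsFactors = FALSE)))
  expect_equal(upstream_interactors("A", cg), "B")
  expect_equal(upstream_interactors("B", cg), "A")
})

test_that("upstream rule agrees with an independent enumeration oracle", {
  g <- demo_graph()
  for (gene in c("BRCA1", "ATM", "TP53", "ESR1", "CDK2", "EP300")) {
    expect_equal(upstream_interactors(gene, g), oracle_upstream(gene, g),
                 info = gene)
  }
  set.seed(7)
  for (rep in 1:10) {
    edges <- random_edges(25)
    class(edges) <- c("interaction_graph", class(edges))
    for (gene in c("G01", "G04", "G08")) {
      expect_equal(upstream_interactors(gene, edges),
                   oracle_upstream(gene, edges))
    }
  }
})

test_that("expansion triggers only without direct hits and respects the level bound", {
  catalog <- indexed_catalog()
  g <- demo_graph()
  # direct hit: no expansion beyond level 0
  ex <- expand_gene_search("EPCAM", 3, g, catalog)
  expect_equal(names(ex$levels), "0")
  expect_equal(expansion_drugs(ex)$drug_id, c("DB05319", "DB05831"))
  # level 0 is extensionally identical to the direct search
  ex0 <- expand_gene_search("BRCA1", 0, g, catalog)
  expect_equal(expansion_drugs(ex0)$drug_id,
               drugs_targeting("BRCA1", catalog)$drug_id)
  # the printed example: flavopiridol reached through CDK7 and CDK9
  ex1 <- expand_gene_search("BRCA1", 1, g, catalog)
  lev1 <- ex1$levels[["1"]]
  expect_equal(lev1[["CDK7"]]$drug_id, "DB03496")
  expect_equal(lev1[["CDK9"]]$drug_id, "DB03496")
  expect_equal(nrow(expansion_drugs(ex1)), 8L)
})

test_that("a drug only two levels up needs max_level 2 (hand-enumerated chain)", {
  # chain A <- B <- C with drugs only on C
  edges <- data.frame(
    source = c("B", "C"), type = "controls-state-change-of",
    target = c("A", "B"), stringsAsFactors = FALSE)
  g <- parse_sif(write_sif(edges))
  entries <- default_drug_entries()[1, ]
  entries$target_genes <- "C"
  f <- tempfile(fileext = ".tsv")
  make_catalog(f, entries)
  catalog <- index_catalog(parse_drug_catalog(f), default_vocab())
  ex1 <- expand_gene_search("A", 1, g, catalog)
  expect_equal(nrow(expansion_drugs(ex1)), 0L)
  ex2 <- expand_gene_search("A", 2, g, catalog)
  flat <- expansion_drugs(ex2)
  expect_equal(flat$drug_id, "DB00317")
  expect_equal(flat$via_genes, "C")
  expect_equal(names(ex2$levels), c("0", "1", "2"))
})

test_that("expansion properties hold on random graphs: oracle match, monotone levels, unique gene levels", {
  catalog <- indexed_catalog()
  set.seed(11)
  # random graphs over genes G01..G08 with a catalog targeting a few of them
  entries <- default_drug_entries()[1:3, ]
  entries$target_genes <- c("G02", "G05;G07", "G08")
  f <- tempfile(fileext = ".tsv")
  make_catalog(f, entries)
  small_catalog <- index_catalog(parse_drug_catalog(f), default_vocab())
  for (rep in 1:12) {
    edges <- random_edges(20)
    class(edges) <- c("interaction_graph", class(edges))
    query <- "G01"
    prev <- character(0)
    for (lev in 0:3) {
      ex <- expand_gene_search(query, lev, edges, small_catalog)
      ids <- expansion_drugs(ex)$drug_id
      expect_equal(ids, oracle_expansion_ids(query, lev, edges,
                                             small_catalog))
      expect_true(all(prev %in% ids))  # monotone in max_level
      prev <- ids
      genes_by_level <- unlist(lapply(ex$levels, names))
      expect_equal(anyDuplicated(genes_by_level), 0L)
      expect_false(query %in% unlist(lapply(ex$levels[-1], names)))
    }
  }
})
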