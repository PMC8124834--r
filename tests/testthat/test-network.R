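# Bipartite miRNA-target network construction, curated neighborhoods,
# GraphML round-trip, reverse-expression screen.

test_that("curated target neighborhoods emerge from the packaged fixture", {
  down <- downregulated_geromirs(platform_catalog())
  net <- build_network(down, synthetic_interactions())
  expect_equal(gene_regulators(net, "Cercam"),
               c("miR-10a", "miR-26a", "miR-26b"))
  expect_equal(gene_regulators(net, "Spsb4"),
               c("miR-15a", "miR-16", "miR-24"))
  # case-insensitive gene lookup
  expect_equal(gene_regulators(net, "CERCAM"),
               gene_regulators(net, "Cercam"))
  # only downregulated miRNAs enter the network
  expect_true(all(mirna_nodes(net) %in% down))
  expect_false("miR-34a" %in% mirna_nodes(net))
  # every downregulated geromiR in the fixture has a target, none isolated
  expect_true(all(igraph::degree(net) > 0))
})

test_that("network construction is bipartite, monotone, and safe on empty input", {
  ints <- synthetic_interactions()
  empty <- build_network(character(0), ints)
  expect_equal(igraph::vcount(empty), 0L)
  small <- build_network(c("miR-10a"), ints)
  big <- build_network(c("miR-10a", "miR-26a", "miR-16"), ints)
  e_small <- network_edges(small); e_big <- network_edges(big)
  expect_true(all(paste(e_small$mirna, e_small$gene) %in%
                    paste(e_big$mirna, e_big$gene)))
  # an identifier on both sides is rejected
  clash <- data.frame(mirna = c("miR-1", "miR-2"),
                      gene = c("Abc", "miR-1"), evidence = "")
  expect_error(build_network(c("miR-1", "miR-2"), clash), "both miRNA and gene")
})

test_that("interaction tables are normalized, deduplicated and evidence-filterable", {
  f <- withr::local_tempfile(lines = c(
    "mirna\tgene\tevidence",
    "mmu-miR-10a\tCercam\tMicroarray",
    "miR-10a\tCercam\tLuciferase",
    "hsa-miR-16\tBCL2\tLuciferase"), fileext = ".tsv")
  ints <- read_interactions(f)
  expect_equal(nrow(ints), 2L)  # duplicate (miR-10a, Cercam) collapsed
  expect_equal(sort(unique(ints$mirna)), c("miR-10a", "miR-16"))
  # the evidence filter applies before deduplication, so the Luciferase
  # record of the duplicated pair survives
  lucif <- read_interactions(f, evidence_pattern = "Luciferase")
  expect_equal(nrow(lucif), 2L)
  expect_setequal(lucif$gene, c("Cercam", "BCL2"))
  expect_true(all(lucif$evidence == "Luciferase"))
  expect_error(read_interactions(withr::local_tempfile(
    lines = "a\tb", fileext = ".tsv")), "lacks column")
})

test_that("GraphML export and import round-trip the network exactly", {
  down <- downregulated_geromirs(platform_catalog())
  net <- build_network(down, synthetic_interactions())
  gml <- withr::local_tempfile(fileext = ".graphml")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, gml, tsv)
  back <- import_network(gml)
  expect_setequal(mirna_nodes(back), mirna_nodes(net))
  expect_setequal(gene_nodes(back), gene_nodes(net))
  expect_equal(network_edges(back), network_edges(net),
               ignore_attr = TRUE)
  edges_file <- utils::read.delim(tsv, stringsAsFactors = FALSE)
  expect_equal(nrow(edges_file), igraph::ecount(net))
  # empty network round-trips too
  e0 <- build_network(character(0), synthetic_interactions())
  gml0 <- withr::local_tempfile(fileext = ".graphml")
  export_network(e0, gml0)
  expect_equal(igraph::vcount(import_network(gml0)), 0L)
  # a toy 2x2 network has the expected shape
  toy <- build_network(c("miR-x1", "miR-x2"), data.frame(
    mirna = c("miR-x1", "miR-x1", "miR-x2"),
    gene = c("GeneA", "GeneB", "GeneA"), evidence = ""))
  expect_equal(igraph::vcount(toy), 4L)
  expect_equal(igraph::ecount(toy), 3L)
})

test_that("the reverse-expression screen returns exactly the planted upregulated targets", {
  ds <- simulate_dataset(simulation_config(seed = 77L))
  # screen against a network over all downregulated calls so every planted
  # gene's regulators are candidates
  xq <- quantile_normalize(ds$mirna_matrix)
  dems <- call_dems(xq, ds$mirna_annotation)
  net <- build_network(dem_features(dems, "down"), ds$interactions)
  gq <- quantile_normalize(ds$gene_matrix)
  hits <- reverse_expression_screen(net, gq, ds$gene_annotation)
  expect_setequal(hits$gene,
                  intersect(ds$truth$planted_up_genes, gene_nodes(net)))
  # every linked miRNA is a downregulated network miRNA
  linked <- unlist(strsplit(hits$linked_mirnas, ";"))
  expect_true(all(linked %in% dem_features(dems, "down")))
  # a null gene matrix yields no hits
  null_ds <- simulate_dataset(simulation_config(seed = 78L,
                                                effect_log2 = 0))
  null_hits <- reverse_expression_screen(
    net2 <- net, quantile_normalize(null_ds$gene_matrix),
    null_ds$gene_annotation)
  expect_equal(nrow(null_hits), 0L)
  # genes absent from the matrix -> warning and empty result
  offnet <- build_network("miR-z",
                          data.frame(mirna = "miR-z", gene = "NotMeasured",
                                     evidence = ""))
  expect_warning(
    none <- reverse_expression_screen(offnet, gq, ds$gene_annotation),
    "no network gene")
  expect_equal(nrow(none), 0L)
  # an upregulated gene outside the network is not reported
  up_outside <- setdiff(ds$truth$planted_up_genes, gene_nodes(net))
  expect_true(all(!up_outside %in% hits$gene))
})
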