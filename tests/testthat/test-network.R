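mk_net_inputs <- function() {
  ppi <- data.frame(gene_a = c("g1", "g1"), gene_b = c("g2", "g3"),
                    n_methods = 2L, n_pubs = 1L,
                    high_confidence = TRUE,
                    direct_physical = c(TRUE, FALSE),
                    stringsAsFactors = FALSE)
  mti <- data.frame(mirna_id = "mir-1", gene_id = "g1",
                    evidence_class = "Functional MTI", pmid = "1",
                    stringsAsFactors = FALSE)
  pci <- data.frame(skeleton = c("SKEL1", "SKEL2"),
                    protein_id = c("g1", "g1"),
                    best_activity_nM = c(500, 5000),
                    annotation_only = FALSE, has_annotation = c(FALSE, TRUE),
                    source_dbs = "ChEMBL", stringsAsFactors = FALSE)
  tf <- data.frame(tf_gene_id = "g9", target_gene_id = "g1",
                   source_db = "tfdb", stringsAsFactors = FALSE)
  list(ppi = ppi, mti = mti, pci = pci, tf = tf)
}

test_that("composite network merges one-hop typed edges around the query", {
  x <- mk_net_inputs()
  net <- build_network(gene_list(c("g1", "g2")), ppi = x$ppi, mti = x$mti,
                       pci = x$pci[1, ], tf = NULL)
  # g3 edge excluded: high-confidence but not direct-physical
  expect_false("g3" %in% net$nodes$node_id)
  expect_equal(nrow(net$nodes), 4L)  # g1, g2, mir-1, SKEL1
  expect_equal(nrow(net$edges), 3L)
  expect_setequal(net$edges$edge_type, c("ppi", "mti", "pci"))
  kinds <- setNames(net$nodes$node_kind, net$nodes$node_id)
  expect_equal(unname(kinds["mir-1"]), "mirna")
  expect_equal(unname(kinds["SKEL1"]), "compound_group")
  empty <- gene_list("x")
  empty$members <- character(0)
  expect_error(build_network(empty), "empty query")
})

test_that("same gene pair can carry edges of two types; rebuild is idempotent", {
  ppi <- data.frame(gene_a = "g1", gene_b = "g9", n_methods = 2L,
                    n_pubs = 2L, high_confidence = TRUE,
                    direct_physical = TRUE, stringsAsFactors = FALSE)
  tf <- data.frame(tf_gene_id = "g9", target_gene_id = "g1",
                   source_db = "tfdb", stringsAsFactors = FALSE)
  net <- build_network(gene_list("g1"), ppi = ppi, tf = tf)
  expect_equal(nrow(net$edges), 2L)
  expect_setequal(net$edges$edge_type, c("ppi", "tf_target"))
  net2 <- build_network(gene_list("g1"), ppi = ppi, tf = tf)
  expect_identical(net, net2)
  # type partition: per-type counts sum to the total
  expect_equal(nrow(net$edges), sum(table(net$edges$edge_type)))
})

test_that("activity filtering scopes to assay-backed PCI edges and prunes", {
  x <- mk_net_inputs()
  net <- build_network(gene_list("g1"), ppi = x$ppi, mti = x$mti,
                       pci = x$pci, tf = x$tf)
  f <- filter_activity(net, max_nM = 1000)
  # 500 nM edge kept; 5000 nM edge kept only via its drug annotation
  expect_setequal(f$edges$to[f$edges$edge_type == "pci"],
                  c("SKEL1", "SKEL2"))
  x$pci$has_annotation <- FALSE
  net2 <- build_network(gene_list("g1"), ppi = x$ppi, mti = x$mti,
                        pci = x$pci, tf = x$tf)
  f2 <- filter_activity(net2, max_nM = 1000)
  expect_false("SKEL2" %in% f2$nodes$node_id)  # orphan pruned
  expect_equal(sum(f2$edges$edge_type == "mti"), 1L)  # other types untouched
  # query gene survives even if fully isolated
  solo <- build_network(gene_list("g1"), pci = x$pci)
  fs <- filter_activity(solo, max_nM = 1)
  expect_true("g1" %in% fs$nodes$node_id)
  expect_equal(nrow(fs$edges), 0L)
})

test_that("exports produce SIF lines, importable GraphML and Cytoscape JSON", {
  x <- mk_net_inputs()
  net <- build_network(gene_list("g1"), ppi = x$ppi, mti = x$mti,
                       pci = x$pci, tf = x$tf)
  sif <- withr::local_tempfile(fileext = ".sif")
  export_network(net, sif, "sif")
  expect_equal(length(readLines(sif)), nrow(net$edges))

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, gml, "graphml")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_setequal(igraph::V(g)$name, net$nodes$node_id)
  el <- igraph::as_edgelist(g)
  expect_setequal(paste(el[, 1], el[, 2]),
                  paste(net$edges$from, net$edges$to))

  js <- withr::local_tempfile(fileext = ".json")
  export_network(net, js, "json")
  parsed <- jsonlite::read_json(js)
  expect_equal(length(parsed$elements$nodes), nrow(net$nodes))
  expect_equal(length(parsed$elements$edges), nrow(net$edges))
  expect_error(export_network(net, sif, "dot"))
  # empty network still exports valid files
  empty <- build_network(gene_list("lonely"))
  export_network(empty, js, "json")
  expect_equal(length(jsonlite::read_json(js)$elements$edges), 0L)
})
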