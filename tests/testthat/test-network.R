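toy_contrast <- function() {
  recs <- data.frame(
    transcript_id = c("L1", "L2", "M1", "M2", "M3"),
    symbol = c("LNC1", "LNC2", "GENE1", "GENE2", "GENE3"),
    biotype = c("antisense", "lincRNA", rep("protein_coding", 3)),
    log2fc = c(1, -2, 0.8, -0.9, 1.1),
    p = 0.001, q = 0.01, stringsAsFactors = FALSE)
  classify_biotypes(filter_significant(recs, filter_spec(0.1, 1.5)), "toy")
}

test_that("build_network keeps exactly the doubly significant edges", {
  ct <- toy_contrast()
  inter <- data.frame(
    lncrna_id = c("L1", "L1", "L1", "L9"),
    mrna_id = c("M1", "M3", "MX", "M1"),
    stringsAsFactors = FALSE)
  net <- build_network(ct, inter)
  expect_equal(nrow(net$edges), 2L)
  expect_equal(nrow(net$lncrna_nodes), 1L)
  expect_equal(nrow(net$mrna_nodes), 2L)
  # direction copied from the DE sign
  expect_equal(net$lncrna_nodes$direction, "up")
  expect_setequal(net$mrna_nodes$direction, c("up"))
  # disjoint IDs -> empty network; L2 had no surviving edge and is dropped
  empty <- build_network(ct, data.frame(lncrna_id = "zz", mrna_id = "yy"))
  expect_equal(nrow(empty$edges), 0L)
  expect_false("L2" %in% net$lncrna_nodes$id)
})

test_that("degree ranking matches a brute-force edge count", {
  ct <- toy_contrast()
  net <- build_network(ct, data.frame(lncrna_id = "L1", mrna_id = "M1"))
  r <- rank_by_centrality(net, top_k = 1L)
  expect_equal(r$degree, 1L)
  expect_equal(r$rank, 1L)

  s <- sim_network(test_config(seed = 13L))
  ranked <- rank_by_centrality(s$network, top_k = 3L)
  brute <- vapply(ranked$lncrna_id, function(l) {
    length(unique(s$network$edges$mrna_id[s$network$edges$lncrna_id == l]))
  }, integer(1))
  expect_equal(ranked$degree, unname(brute))
  expect_true(all(diff(ranked$degree) <= 0))
  # planted hubs occupy the top ranks
  expect_setequal(ranked$lncrna_id[1:3], s$it$truth$hub_ids)
  # bipartite handshake: lncRNA degrees sum to the edge count, which
  # equals the mRNA in-degree sum
  expect_equal(sum(ranked$degree), nrow(s$network$edges))
  expect_equal(sum(table(s$network$edges$mrna_id)),
               nrow(s$network$edges))
})

test_that("degree ties break lexicographically and top_k overflow warns", {
  ct <- toy_contrast()
  inter <- data.frame(lncrna_id = c("L2", "L1"), mrna_id = c("M1", "M1"))
  net <- build_network(ct, inter)
  r <- rank_by_centrality(net, top_k = 2L)
  expect_equal(r$lncrna_id, c("L1", "L2"))
  expect_warning(rank_by_centrality(net, top_k = 5L), "top_k")
})

test_that("target sets agree with node degrees and share targets once", {
  s <- sim_network(test_config(seed = 21L))
  ts <- target_sets(s$network)
  ranked <- rank_by_centrality(s$network)
  expect_equal(vapply(ts[ranked$lncrna_id], length, integer(1)),
               stats::setNames(ranked$degree, ranked$lncrna_id))
  expect_equal(length(unique(unlist(ts))), nrow(s$network$mrna_nodes))
  expect_length(target_sets(build_network(toy_contrast(),
    data.frame(lncrna_id = "zz", mrna_id = "yy"))), 0L)
  # a shared target is in both sets but counted once in the union
  ct <- toy_contrast()
  net2 <- build_network(ct, data.frame(lncrna_id = c("L1", "L2"),
                                       mrna_id = c("M2", "M2")))
  ts2 <- target_sets(net2)
  expect_equal(ts2$L1, "M2")
  expect_equal(ts2$L2, "M2")
  expect_equal(length(unique(unlist(ts2))), 1L)
})

test_that("band annotation left-joins with first-wins deduplication", {
  ct <- toy_contrast()
  net <- build_network(ct, data.frame(lncrna_id = "L1", mrna_id = "M1"))
  r <- rank_by_centrality(net, 1L)
  expect_equal(annotate_locations(r, data.frame(id = character(0),
                                                band = character(0)))$
                 chromosome_band, "")
  band <- data.frame(id = "LNC1", band = "Xq13.2")
  expect_equal(suppressMessages(annotate_locations(r, band))$
                 chromosome_band, "Xq13.2")
  dup <- data.frame(id = c("L1", "L1"), band = c("1p1", "2q2"))
  expect_warning(out <- annotate_locations(r, dup), "duplicated")
  expect_equal(out$chromosome_band, "1p1")
})

test_that("SIF and TSV exports round-trip the network", {
  s <- sim_network(test_config(seed = 2L))
  sif <- withr::local_tempfile(fileext = ".sif")
  export_edges(s$network, sif, "sif")
  lines <- readLines(sif)
  expect_length(lines, nrow(s$network$edges))
  expect_true(all(lengths(strsplit(lines, "\t")) == 3L))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_edges(s$network, tsv, "tsv")
  back <- import_network_tsv(tsv, label = s$network$label)
  expect_equal(back$edges, s$network$edges)
  expect_equal(back$lncrna_nodes, s$network$lncrna_nodes)
  expect_equal(back$mrna_nodes, s$network$mrna_nodes)
  expect_error(export_edges(s$network, tsv, "graphml"))

  # single-edge network -> single SIF line with the fallback interaction
  ct <- toy_contrast()
  net1 <- build_network(ct, data.frame(lncrna_id = "L1", mrna_id = "M1"))
  export_edges(net1, sif, "sif")
  expect_equal(readLines(sif), "L1\tregulates\tM1")
})
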