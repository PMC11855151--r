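test_that("degenerate configurations give empty or trivial outputs", {
  cfg <- sim_config(n_transcripts = 0L, n_significant = 0L,
                    n_hub_lncrnas = 0L, n_equivalence_blocks = 0L)
  de <- simulate_de_table(cfg)
  expect_equal(nrow(de$table), 0L)
  expect_length(de$truth$significant_ids, 0L)

  cfg0 <- test_config(alteration_base_rate = 0)
  alt <- simulate_alteration_matrix(cfg0)
  expect_true(all(alt$matrix == 0L))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_significant = 10, n_transcripts = 5),
               "n_significant")
  expect_error(sim_config(hub_degree = 5, background_degree_max = 10),
               "hub_degree")
  expect_error(sim_config(lncrna_fraction = 1.2), "proportion")
  expect_error(sim_config(planted_pair_odds_ratio = 0), "positive")
  # hub degree larger than the significant mRNA pool
  cfg <- test_config(hub_degree = 5000L)
  de <- simulate_de_table(cfg)
  expect_error(simulate_interaction_table(cfg, de), "significant mRNAs")
})

test_that("all generators are deterministic in the seed", {
  cfg <- test_config(seed = 7L)
  expect_identical(simulate_de_table(cfg, "x")$table,
                   simulate_de_table(cfg, "x")$table)
  de <- simulate_de_table(cfg, "x")
  expect_identical(simulate_interaction_table(cfg, de)$table,
                   simulate_interaction_table(cfg, de)$table)
  expect_identical(simulate_alteration_matrix(cfg)$matrix,
                   simulate_alteration_matrix(cfg)$matrix)
  it <- simulate_interaction_table(cfg, de)
  expect_identical(make_gene_sets(cfg, de, it)$collection$sets,
                   make_gene_sets(cfg, de, it)$collection$sets)
  # a different seed actually changes the draw
  expect_false(identical(
    simulate_de_table(test_config(seed = 8L), "x")$table$pvalue,
    de$table$pvalue))
})

test_that("planted DE signals pass the significance filter and little else", {
  for (seed in c(3L, 11L)) {
    cfg <- sim_config(n_transcripts = 1000L, n_significant = 100L,
                      lncrna_fraction = 0.3, n_hub_lncrnas = 0L,
                      n_equivalence_blocks = 0L, seed = seed)
    de <- simulate_de_table(cfg)
    # oracle: count directly on the emitted table
    direct <- sum(de$table$padj <= 0.1 &
                    abs(de$table$log2FoldChange) >= log2(1.5))
    sig <- filter_significant(as_records(de$table), filter_spec(0.1, 1.5))
    expect_equal(nrow(sig), direct)
    # every planted row is recovered; BH false positives stay small
    expect_true(all(de$truth$significant_ids %in% sig$transcript_id))
    expect_lte(nrow(sig) - 100L, 20L)
    # biotype fraction is planted exactly
    expect_equal(sum(de$table$biotype %in% lncrna_biotypes()), 300L)
    lnc_share <- mean(sig$biotype %in% lncrna_biotypes())
    expect_gt(lnc_share, 0.15)
    expect_lt(lnc_share, 0.45)
  }
})

test_that("with no planted signal the BH discovery fraction is controlled", {
  fracs <- vapply(1:5, function(seed) {
    cfg <- sim_config(n_transcripts = 800L, n_significant = 0L,
                      n_hub_lncrnas = 0L, n_equivalence_blocks = 0L,
                      seed = seed)
    de <- simulate_de_table(cfg)
    mean(de$table$padj <= 0.1)
  }, numeric(1))
  expect_lte(mean(fracs), 0.1 * 1.05)
})

test_that("interaction tables carry the planted hubs and blocks", {
  cfg <- test_config(seed = 5L)
  de <- simulate_de_table(cfg)
  it <- simulate_interaction_table(cfg, de)
  expect_false(any(duplicated(it$table[c("lncrna_id", "mrna_id")])))
  # every referenced ID exists in the DE table
  expect_true(all(it$table$lncrna_id %in% de$table$transcript_id))
  expect_true(all(it$table$mrna_id %in% de$table$transcript_id))
  deg <- table(it$table$lncrna_id)
  for (h in it$truth$hub_ids) expect_equal(unname(deg[h]), 50L)
  # blocks with full overlap have identical target sets
  cfg1 <- test_config(seed = 5L, block_target_overlap = 1.0)
  it1 <- simulate_interaction_table(cfg1, de)
  for (b in it1$truth$equivalence_blocks) {
    sets <- lapply(b, function(l) sort(it1$table$mrna_id[
      it1$table$lncrna_id == l]))
    for (s in sets[-1]) expect_identical(s, sets[[1]])
  }
  # partial overlap: shared fraction of each member's targets >= planted
  for (b in it$truth$equivalence_blocks) {
    sets <- lapply(b, function(l) it$table$mrna_id[it$table$lncrna_id == l])
    core <- Reduce(intersect, sets)
    for (s in sets) expect_gte(length(core) / length(s), 0.9)
  }
})

test_that("the alteration generator hits the planted odds ratio", {
  # null pair: OR estimate near 1 on a large sample
  cfg1 <- test_config(seed = 2L, planted_pair_odds_ratio = 1,
                      n_samples = 50000L)
  m1 <- simulate_alteration_matrix(cfg1)$matrix
  ct1 <- contingency(m1, "ALT01", "ALT02")
  or1 <- (ct1["both"] * ct1["neither"]) / (ct1["a_not_b"] * ct1["b_not_a"])
  expect_lt(abs(unname(or1) - 1), 0.05 * 8)  # sampling noise around 1
  # margins stay at the base rate
  expect_lt(abs(mean(m1[, "ALT01"]) - 0.05), 0.01)

  cfg16 <- test_config(seed = 2L, n_samples = 50000L)
  m16 <- simulate_alteration_matrix(cfg16)$matrix
  ct16 <- contingency(m16, "ALT01", "ALT02")
  l2 <- log2((ct16["both"] * ct16["neither"]) /
               (ct16["a_not_b"] * ct16["b_not_a"]))
  expect_lt(abs(unname(l2) - 4), 0.15)
})

test_that("GMT round-trips preserve names, order and membership", {
  coll <- gene_set_collection(
    list(alpha = c("g1", "g2", "g3"), beta = c("g2", "g4")),
    descriptions = c("first", "second"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(coll, path)
  back <- read_gmt(path)
  expect_identical(names(back$sets), c("alpha", "beta"))
  expect_identical(back$sets, coll$sets)
  expect_identical(unname(back$descriptions), c("first", "second"))
  # independent reader agrees on membership
  fg <- fgsea::gmtPathways(path)
  expect_identical(lapply(fg, sort), lapply(coll$sets, sort))
  # empty collection -> empty file
  p2 <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(gene_set_collection(setNames(list(), character(0))), p2)
  expect_length(readLines(p2), 0L)
  expect_error(gene_set_collection(list(a = "g1", a = "g2")), "duplicate")
})

test_that("planted enriched sets win the ORA ranking", {
  wins <- vapply(c(1L, 4L, 9L), function(seed) {
    cfg <- test_config(seed = seed)
    de <- simulate_de_table(cfg)
    it <- simulate_interaction_table(cfg, de)
    gs <- make_gene_sets(cfg, de, it)
    hub <- it$truth$hub_ids[1L]
    res <- suppressMessages(ora(it$truth$hub_targets[[hub]],
                                gs$collection))
    res$set[1L] %in% gs$truth$enriched_set_names
  }, logical(1))
  expect_true(all(wins))
})
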