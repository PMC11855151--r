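# Naive agglomerative clustering oracle: returns the cophenetic distance
# matrix for average/complete/single linkage by direct cluster merging.
naive_agglomerative <- function(d, linkage = "average") {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  active <- rep(TRUE, n)
  dist_between <- function(a, b) {
    vals <- d[clusters[[a]], clusters[[b]], drop = FALSE]
    switch(linkage, average = mean(vals), complete = max(vals),
           single = min(vals))
  }
  while (sum(active) > 1L) {
    idx <- which(active)
    best <- c(NA, NA); best_d <- Inf
    for (i in idx) for (j in idx) {
      if (i < j) {
        dij <- dist_between(i, j)
        if (dij < best_d) { best_d <- dij; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    coph[clusters[[i]], clusters[[j]]] <- best_d
    coph[clusters[[j]], clusters[[i]]] <- best_d
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    active[j] <- FALSE
  }
  coph
}

test_that("similarity metrics match their set-overlap definitions", {
  ts <- list(a = c("x", "y", "z"), b = c("y", "z", "w"),
             c = c("x", "y", "z"), d = "q", e = character(0))
  sim <- similarity_matrix(ts, "jaccard")
  expect_equal(sim["a", "b"], 2 / 4)
  expect_equal(sim["a", "c"], 1)       # identical non-empty sets
  expect_equal(sim["a", "d"], 0)       # disjoint
  expect_equal(sim["a", "e"], 0)       # empty partner
  expect_equal(diag(sim), c(a = 1, b = 1, c = 1, d = 1, e = 0))
  expect_equal(similarity_matrix(ts, "dice")["a", "b"], 2 * 2 / 6)
  expect_equal(similarity_matrix(ts, "cosine")["a", "b"], 2 / 3)
  expect_error(similarity_matrix(ts, "hamming"))
})

test_that("similarity matrices are symmetric, bounded, and 1 iff equal", {
  set.seed(31)
  for (rep in 1:5) {
    ts <- random_target_sets(12, 40, 15)
    sim <- similarity_matrix(ts)
    expect_true(isSymmetric(unname(sim)))
    expect_true(all(sim >= 0 & sim <= 1))
    ones <- which(sim == 1 & upper.tri(sim), arr.ind = TRUE)
    for (k in seq_len(nrow(ones))) {
      expect_setequal(ts[[ones[k, 1]]], ts[[ones[k, 2]]])
    }
  }
})

test_that("clustering agrees with a brute-force agglomerative oracle", {
  set.seed(17)
  for (linkage in c("average", "complete", "single")) {
    for (rep in 1:4) {
      n <- sample(4:8, 1)
      ts <- random_target_sets(n, 25, 12)
      sim <- similarity_matrix(ts)
      hc <- cluster_lncrnas(sim, linkage)
      got <- as.matrix(stats::cophenetic(hc))
      ids <- rownames(sim)
      want <- naive_agglomerative(1 - sim, linkage)
      dimnames(want) <- dimnames(sim)
      expect_equal(got[ids, ids], want, tolerance = 1e-10)
    }
  }
  # two items: a single merge at their distance
  ts2 <- list(a = c("x", "y"), b = c("y", "z"))
  hc2 <- cluster_lncrnas(similarity_matrix(ts2))
  expect_equal(hc2$height, 1 - 1 / 3)
  expect_warning(cluster_lncrnas(similarity_matrix(list(a = "x"))),
                 "fewer than 2")
})

test_that("clustering is invariant under input permutation", {
  set.seed(23)
  ts <- random_target_sets(10, 30, 12)
  hc1 <- cluster_lncrnas(similarity_matrix(ts))
  perm <- sample(names(ts))
  hc2 <- cluster_lncrnas(similarity_matrix(ts[perm]))
  c1 <- as.matrix(stats::cophenetic(hc1))
  c2 <- as.matrix(stats::cophenetic(hc2))
  expect_equal(c2[rownames(c1), colnames(c1)], c1, tolerance = 1e-12)
  # Newick export parses back to the same topology
  nwk <- dendrogram_newick(hc1)
  tree <- ape::read.tree(text = nwk)
  expect_setequal(tree$tip.label, names(ts))
})

test_that("planted blocks come out as clades and threshold groups", {
  cfg <- test_config(seed = 3L, block_target_overlap = 1.0)
  s <- sim_network(cfg)
  ts <- target_sets(s$network)
  sim <- similarity_matrix(ts)
  hc <- cluster_lncrnas(sim)
  # identical target sets merge at height 0: cutting just above zero
  # puts each block in one cluster
  cl <- stats::cutree(hc, h = 1e-9)
  for (b in s$it$truth$equivalence_blocks) {
    expect_length(unique(cl[b]), 1L)
  }
  groups <- extract_groups(sim, ts, threshold = 0.9)
  members <- lapply(groups, `[[`, "member_ids")
  for (b in s$it$truth$equivalence_blocks) {
    expect_true(any(vapply(members, identical, logical(1), sort(b))))
  }
})

test_that("group extraction honours thresholds and computes cores", {
  ts <- list(a = c("x", "y", "z"), b = c("x", "y", "w"), c = "k")
  sim <- similarity_matrix(ts)  # sim(a,b) = 0.5
  expect_length(extract_groups(sim, ts, threshold = 1.0), 0L)
  g <- extract_groups(sim, ts, threshold = 0.5)
  expect_length(g, 1L)
  expect_equal(g[[1]]$member_ids, c("a", "b"))
  expect_equal(g[[1]]$shared_target_core, c("x", "y"))
  expect_equal(g[[1]]$mean_within_similarity, 0.5)
})

test_that("lowering the threshold never splits an existing group", {
  set.seed(41)
  for (rep in 1:5) {
    ts <- random_target_sets(15, 30, 10)
    sim <- similarity_matrix(ts)
    hi <- extract_groups(sim, ts, threshold = 0.6)
    lo <- extract_groups(sim, ts, threshold = 0.3)
    lo_members <- lapply(lo, `[[`, "member_ids")
    for (g in hi) {
      containing <- vapply(lo_members, function(m) {
        all(g$member_ids %in% m)
      }, logical(1))
      expect_equal(sum(containing), 1L)
    }
  }
})

test_that("most similar pair equals an exhaustive scan", {
  ts <- list(a = c("x", "y"), b = c("x", "y"))
  sim <- similarity_matrix(ts)
  expect_equal(most_similar_pair(sim),
               list(pair = c("a", "b"), similarity = 1))
  expect_error(most_similar_pair(sim, restrict_to = "a"), "at least 2")

  set.seed(53)
  ts10 <- random_target_sets(10, 30, 12)
  sim10 <- similarity_matrix(ts10)
  got <- most_similar_pair(sim10)
  best <- -Inf; best_pair <- NULL
  for (i in 1:9) for (j in (i + 1):10) {
    if (sim10[i, j] > best) {
      best <- sim10[i, j]
      best_pair <- sort(c(rownames(sim10)[i], colnames(sim10)[j]))
    }
  }
  expect_equal(got$similarity, best)
  expect_equal(got$pair, best_pair)
  # restriction works
  sub <- names(ts10)[1:4]
  got_sub <- most_similar_pair(sim10, restrict_to = sub)
  expect_true(all(got_sub$pair %in% sub))
})
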