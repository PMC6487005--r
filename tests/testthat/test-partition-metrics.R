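test_that("modularity matches worked values and the naive evaluator", {
  tt <- two_triangle_graph()
  expect_equal(modularity_q(tt, two_triangle_partition()), 5 / 14)
  # single community of any graph scores exactly zero
  expect_equal(modularity_q(tt, partition(
    stats::setNames(rep("x", 6), as.character(1:6)))), 0)
  # K4 2+2 split
  k4 <- complete_graph(4)
  p22 <- partition(stats::setNames(c("x", "x", "y", "y"),
                                   paste0("k", 1:4)))
  expect_equal(modularity_q(k4, p22), -1 / 6)
  expect_error(modularity_q(tt, p22), "does not cover")

  # community-form vs naive double-loop on random graphs/partitions
  for (seed in 1:5) {
    g <- random_connected_graph(12, 0.3, seed = seed)
    p <- random_partition(igraph::V(g)$name, 3, seed = seed + 100)
    expect_equal(modularity_q(g, p), naive_modularity_p(g, p),
                 tolerance = 1e-12)
  }
})

test_that("RI, ARI and NMI agree with pair counting and known cases", {
  # worked 4-node example: pA = {a,b | c,d}, pB = {a,b,c | d}
  pa <- partition(stats::setNames(c("1", "1", "2", "2"), letters[1:4]))
  pb <- partition(stats::setNames(c("1", "1", "1", "2"), letters[1:4]))
  cmp <- compare_partitions(pa, pb)
  expect_equal(cmp$ri, 0.5)
  expect_equal(unname(cmp$pair_counts["n11"] + cmp$pair_counts["n00"]), 3)

  # self-comparison of any multi-community partition
  cmp_self <- compare_partitions(pa, pa)
  expect_equal(c(cmp_self$ri, cmp_self$ari, cmp_self$nmi), c(1, 1, 1))

  # degenerate: singletons vs one community
  ps <- partition(stats::setNames(as.character(1:4), letters[1:4]))
  po <- partition(stats::setNames(rep("c", 4), letters[1:4]))
  cmp_d <- compare_partitions(ps, po)
  expect_equal(c(cmp_d$ri, cmp_d$ari, cmp_d$nmi), c(0, 0, 0))

  expect_error(
    compare_partitions(pa, partition(stats::setNames("1", "zz"))),
    "different node sets")

  # random partitions: pair counts match brute-force pair enumeration,
  # metrics are symmetric, probabilistic RI form holds
  for (seed in 1:5) {
    nodes <- paste0("n", 1:12)
    pa <- random_partition(nodes, 3, seed)
    pb <- random_partition(nodes, 4, seed + 50)
    cmp <- compare_partitions(pa, pb)
    pc <- naive_pair_counts(pa, pb)
    expect_equal(cmp$pair_counts, pc)
    expect_equal(cmp$ri, (pc["n00"] + pc["n11"]) / choose(12, 2),
                 ignore_attr = TRUE)
    rev <- compare_partitions(pb, pa)
    expect_equal(cmp$ri, rev$ri)
    expect_equal(cmp$ari, rev$ari)
    expect_equal(cmp$nmi, rev$nmi)
  }
})

test_that("ARI and NMI match independent implementations", {
  skip_if_not_installed("mclust")
  for (seed in 1:4) {
    nodes <- paste0("n", 1:60)
    pa <- random_partition(nodes, 5, seed)
    pb <- random_partition(nodes, 4, seed + 9)
    cmp <- compare_partitions(pa, pb)
    la <- as.integer(factor(pa$membership[nodes]))
    lb <- as.integer(factor(pb$membership[nodes]))
    expect_equal(cmp$ari, mclust::adjustedRandIndex(la, lb),
                 tolerance = 1e-12)
    expect_equal(cmp$ari, igraph::compare(la, lb, "adjusted.rand"),
                 tolerance = 1e-12)
    expect_equal(cmp$nmi, igraph::compare(la, lb, "nmi"),
                 tolerance = 1e-12)
  }
})

test_that("NMI is invariant to community relabeling", {
  nodes <- paste0("n", 1:40)
  pa <- random_partition(nodes, 4, 3)
  pb <- random_partition(nodes, 3, 8)
  relab <- partition(stats::setNames(
    paste0("community_", pa$membership), names(pa$membership)))
  expect_equal(compare_partitions(pa, pb)$nmi,
               compare_partitions(relab, pb)$nmi)
})

test_that("ARI of independent random labelings concentrates near zero", {
  aris <- vapply(1:200, function(seed) {
    nodes <- paste0("n", 1:200)
    pa <- random_partition(nodes, 5, seed)
    pb <- random_partition(nodes, 5, seed + 1000)
    compare_partitions(pa, pb)$ari
  }, numeric(1))
  expect_lt(abs(mean(aris)), 0.05)
})

test_that("Jaccard index and matrix behave on sets and partitions", {
  expect_equal(jaccard_index(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(jaccard_index(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard_index(c("a"), c("b")), 0)
  expect_equal(jaccard_index(character(0), character(0)), 0)

  # self-comparison with blocks 150 and 120 at min_size 100
  nodes <- paste0("g", 1:270)
  p <- partition(stats::setNames(rep(c("big", "small"), c(150, 120)),
                                 nodes))
  jm <- jaccard_matrix(p, p, min_size = 100)
  expect_equal(dim(jm), c(2L, 2L))
  expect_equal(rownames(jm), c("big", "small")) # size-sorted
  expect_equal(unname(diag(jm)), c(100, 100))
  expect_true(all(jm[row(jm) != col(jm)] == 0))

  expect_equal(dim(jaccard_matrix(p, p, min_size = 1000)), c(0L, 0L))
})

test_that("community matching picks the column-wise argmax", {
  jm <- matrix(c(100, 0, 0, 100), 2, 2,
               dimnames = list(c("r1", "r2"), c("c1", "c2")))
  m <- match_communities(jm)
  expect_equal(m$row, c("r1", "r2"))
  expect_equal(m$jaccard_pct, c(100, 100))

  jm2 <- matrix(c(40, 70, 10), 3, 1,
                dimnames = list(c("r1", "r2", "r3"), "c1"))
  expect_equal(match_communities(jm2)$row, "r2")
  expect_equal(match_communities(jm2)$jaccard_pct, 70)

  jm3 <- matrix(0, 2, 1, dimnames = list(c("r1", "r2"), "c1"))
  m3 <- match_communities(jm3)
  expect_true(m3$no_overlap)
  expect_equal(m3$jaccard_pct, 0)

  expect_equal(nrow(match_communities(matrix(numeric(0), 0, 0))), 0L)
})

test_that("overlap percentage reproduces every printed worked value", {
  # (size_a, size_b, common) -> printed percent
  cases <- rbind(
    c(151, 141, 139, 92),   # ribosome, second communities
    c(346, 253, 224, 65),   # metabolic pathways, dissimilar pair
    c(406, 273, 239, 59),   # pooled enriched genes, dissimilar pair
    c(77, 71, 70, 91),      # cell cycle, fourth communities
    c(151, 112, 104, 69),   # ribosome, cross-species
    c(1062, 1103, 957, 87), # pooled GO-enriched genes, similar pair
    c(102, 99, 98, 96),     # oxidative phosphorylation
    c(778, 756, 696, 89),   # pooled enriched genes, similar pair
    c(380, 233, 218, 57),   # pooled enriched genes, cross-species
    c(346, 230, 173, 50),   # metabolic pathways, second dissimilar pair
    c(1062, 662, 474, 45)   # pooled GO-enriched genes, dissimilar pair
  )
  for (r in seq_len(nrow(cases))) {
    expect_equal(overlap_percent(cases[r, 1], cases[r, 2], cases[r, 3]),
                 cases[r, 4])
  }
  expect_equal(overlap_percent(7, 7, 7), 100)
  expect_error(overlap_percent(5, 5, 6), "common")
  expect_error(overlap_percent(0, 0, 0), "non-empty")
})
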