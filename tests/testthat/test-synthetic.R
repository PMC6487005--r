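test_that("degenerate probabilities give fully deterministic structure", {
  fx <- planted_partition_graph(c(3, 3), p_in = 1, p_out = 0, seed = 1)
  expect_equal(igraph::vcount(fx$graph), 6L)
  expect_equal(igraph::ecount(fx$graph), 6L)
  comps <- connected_components(fx$graph)
  expect_equal(unname(lengths(comps)), c(3L, 3L))
  expect_equal(blocks_sorted(fx$truth),
               unname(lapply(comps, sort)))
})

test_that("the same seed regenerates the identical edge set", {
  a <- planted_partition_graph(c(20, 20), 0.3, 0.02, seed = 5)
  b <- planted_partition_graph(c(20, 20), 0.3, 0.02, seed = 5)
  expect_identical(igraph::as_edgelist(a$graph), igraph::as_edgelist(b$graph))
  c <- planted_partition_graph(c(20, 20), 0.3, 0.02, seed = 6)
  expect_false(identical(igraph::as_edgelist(a$graph),
                         igraph::as_edgelist(c$graph)))
})

test_that("generated graphs are simple and undirected for any draw", {
  for (seed in 1:6) {
    fx <- planted_partition_graph(c(15, 10, 5), 0.4, 0.05, seed = seed,
                                  heterogeneous = seed %% 2 == 0)
    g <- fx$graph
    expect_false(igraph::any_loop(g))
    expect_false(igraph::any_multiple(g))
    expect_false(igraph::is_directed(g))
    expect_setequal(names(fx$truth$membership), igraph::V(g)$name)
  }
})

test_that("realized densities track p_in and p_out", {
  sizes <- c(40, 40)
  p_in <- 0.25
  p_out <- 0.02
  intra_pairs <- 2 * choose(40, 2)
  inter_pairs <- 40 * 40
  intra <- inter <- numeric(20)
  for (seed in 1:20) {
    fx <- planted_partition_graph(sizes, p_in, p_out, seed = seed)
    el <- igraph::as_edgelist(fx$graph)
    same <- fx$truth$membership[el[, 1]] == fx$truth$membership[el[, 2]]
    intra[seed] <- sum(same) / intra_pairs
    inter[seed] <- sum(!same) / inter_pairs
  }
  se_in <- sqrt(p_in * (1 - p_in) / (20 * intra_pairs))
  se_out <- sqrt(p_out * (1 - p_out) / (20 * inter_pairs))
  expect_lt(abs(mean(intra) - p_in), 4 * se_in)
  expect_lt(abs(mean(inter) - p_out), 4 * se_out)
})

test_that("heterogeneous propensities inflate the degree variance", {
  v_hom <- v_het <- m_hom <- m_het <- numeric(10)
  for (seed in 1:10) {
    hom <- planted_partition_graph(c(60, 60), 0.15, 0.02, seed = seed)
    het <- planted_partition_graph(c(60, 60), 0.15, 0.02, seed = seed,
                                   heterogeneous = TRUE)
    v_hom[seed] <- stats::var(degree_sequence(hom$graph)$degree)
    v_het[seed] <- stats::var(degree_sequence(het$graph)$degree)
    m_hom[seed] <- igraph::ecount(hom$graph)
    m_het[seed] <- igraph::ecount(het$graph)
  }
  expect_gt(mean(v_het), mean(v_hom))
  # expected edge counts comparable (propensities normalized to mean 1)
  expect_lt(abs(mean(m_het) - mean(m_hom)) / mean(m_hom), 0.2)
})

test_that("probability validation rejects inverted densities", {
  expect_error(planted_partition_graph(c(5, 5), 0.1, 0.3, seed = 1),
               "p_out < p_in")
})

test_that("annotations concentrate in home blocks as purity dictates", {
  fx <- planted_partition_graph(c(50, 50, 50), 0.3, 0.02, seed = 2)
  ann_pure <- synthetic_annotation(fx$truth, n_pathways = 12,
                                   size_range = c(15, 30), purity = 1,
                                   seed = 3)
  expect_length(ann_pure$pathways, 12L)
  expect_setequal(ann_pure$universe, names(fx$truth$membership))
  blocks <- partition_blocks(fx$truth)
  for (pw in ann_pure$pathways) {
    in_block <- vapply(blocks, function(b) all(pw %in% b), logical(1))
    expect_equal(sum(in_block), 1L)
  }
  # purity 0: home-block share matches the uniform expectation
  shares <- replicate(20, {
    ann0 <- synthetic_annotation(fx$truth, n_pathways = 1,
                                 size_range = c(30, 30), purity = 0,
                                 seed = sample.int(1e6, 1))
    max(vapply(blocks, function(b)
      length(intersect(ann0$pathways[[1]], b)), numeric(1))) / 30
  })
  # uniform sampling puts about a third in any one block; the max over
  # three blocks sits modestly above that, far from purity-1 behavior
  expect_lt(mean(shares), 0.6)

  ann_none <- synthetic_annotation(fx$truth, n_pathways = 0,
                                   size_range = c(5, 10), seed = 1)
  expect_length(ann_none$pathways, 0L)
  expect_length(ann_none$universe, 150L)
})

test_that("category labels cycle round-robin over pathways", {
  fx <- planted_partition_graph(c(30, 30), 0.4, 0.02, seed = 4)
  ann <- synthetic_annotation(fx$truth, n_pathways = 7,
                              size_range = c(5, 10), purity = 1,
                              n_categories = 3, seed = 5)
  expect_equal(unname(ann$category),
               rep_len(paste0("cat", 1:3), 7))
})

test_that("ortholog tables honour coverage and many-to-many rates", {
  a <- paste0("ya", 1:100)
  b <- paste0("hs", 1:300)
  t0 <- synthetic_ortholog_table(a, b, coverage = 0, seed = 1)
  expect_equal(nrow(t0), 0L)

  t1 <- synthetic_ortholog_table(a, b, coverage = 1,
                                 many_to_many_rate = 0, seed = 1)
  expect_equal(nrow(t1), 100L)
  expect_equal(anyDuplicated(t1$source), 0L)
  expect_equal(anyDuplicated(t1$target), 0L)

  t2 <- synthetic_ortholog_table(a, b, coverage = 0.5,
                                 many_to_many_rate = 0.2, seed = 2)
  expect_equal(length(unique(t2$source)), 50L)
  expect_equal(nrow(t2), 60L) # 10 sources carry a second target
  expect_identical(t2, synthetic_ortholog_table(a, b, 0.5, 0.2, seed = 2))

  expect_error(synthetic_ortholog_table(a, paste0("x", 1:10), 1, 0.5),
               "not enough")
})
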