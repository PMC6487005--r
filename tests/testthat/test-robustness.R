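test_that("node deletion removes exactly the rounded count, seeded", {
  ring <- igraph::make_ring(6532)
  igraph::V(ring)$name <- paste0("n", 1:6532)
  igraph::E(ring)$weight <- rep(1, igraph::ecount(ring))
  pert <- perturb_graph(ring, fraction = 0.01, seed = 3)
  expect_length(pert$removed, 65L) # round(0.01 * 6532)
  expect_equal(igraph::vcount(pert$graph), 6532L - 65L)

  # a fraction rounding to zero returns the graph unchanged
  tiny <- perturb_graph(two_triangle_graph(), fraction = 0.01, seed = 1)
  expect_length(tiny$removed, 0L)
  expect_equal(igraph::vcount(tiny$graph), 6L)

  again <- perturb_graph(ring, fraction = 0.01, seed = 3)
  expect_identical(sort(pert$removed), sort(again$removed))
  expect_error(perturb_graph(two_triangle_graph(), fraction = 0.95),
               "every node")
})

test_that("restricting a partition drops nodes and empty blocks", {
  p <- two_triangle_partition()
  expect_equal(restrict_partition(p, character(0))$membership,
               p$membership)
  gone <- restrict_partition(p, c("4", "5", "6"))
  expect_equal(n_communities(gone), 1L)
  expect_setequal(names(gone$membership), c("1", "2", "3"))
  half <- restrict_partition(p, c("1", "2"))
  expect_equal(unname(table(half$membership)[c("a", "b")]), c(1L, 3L),
               ignore_attr = TRUE)
})

test_that("avg-max Jaccard summarizes column-wise best matches", {
  nodes <- paste0("g", 1:40)
  pa <- partition(stats::setNames(rep(c("x", "y"), each = 20), nodes))
  expect_equal(avg_max_jaccard(pa, pa, min_size = 10), 100)

  # disjoint qualifying blocks -> 0
  pb <- partition(stats::setNames(rep(c("x", "y"), each = 20),
                                  paste0("h", 1:40)))
  expect_equal(avg_max_jaccard(pa, pb, min_size = 10), 0)

  # hand-built column maxima (80, 60) -> mean 70
  ca <- partition(stats::setNames(
    rep(c("r1", "r2"), c(10, 10)), paste0("g", 1:20)))
  cb <- partition(stats::setNames(
    rep(c("c1", "c2"), c(8, 12)),
    paste0("g", c(1:8, 11:18, 9:10, 19:20))))
  jm <- jaccard_matrix(ca, cb, min_size = 5)
  expect_equal(avg_max_jaccard(ca, cb, min_size = 5),
               mean(apply(jm, 2, max)))

  expect_error(avg_max_jaccard(pa, pb, min_size = 100), "undefined")
})

test_that("the statistic is directional: columns are the reference", {
  # one big row community vs two column communities and vice versa
  nodes <- paste0("g", 1:30)
  whole <- partition(stats::setNames(rep("all", 30), nodes))
  halves <- partition(stats::setNames(rep(c("u", "v"), each = 15), nodes))
  a <- avg_max_jaccard(whole, halves, min_size = 10)
  b <- avg_max_jaccard(halves, whole, min_size = 10)
  expect_equal(a, 50)  # each half matched by the whole at J = 50%
  expect_equal(b, 50)  # single column: best of the two halves
  # now make it genuinely asymmetric with unequal halves
  skew <- partition(stats::setNames(rep(c("u", "v"), c(20, 10)), nodes))
  expect_false(
    isTRUE(all.equal(avg_max_jaccard(whole, skew, min_size = 10),
                     avg_max_jaccard(skew, whole, min_size = 10))))
})

test_that("vanishing perturbation keeps a seeded method at 100 percent", {
  fx <- planted_partition_graph(rep(60, 3), 0.3, 0.01, seed = 2)
  det <- detector("louvain")
  rep0 <- robustness_run(fx$graph, det, repeats = 5, fraction = 0.001,
                         min_size = 30, seed = 4)
  expect_true(all(rep0$avg_max == 100))
  expect_equal(rep0$mean, 100)
  expect_equal(rep0$sd, 0)
})

test_that("reports are reproducible and internally consistent", {
  fx <- planted_partition_graph(rep(60, 3), 0.3, 0.01, seed = 5)
  det <- detector("louvain")
  r1 <- robustness_run(fx$graph, det, repeats = 6, fraction = 0.05,
                       min_size = 30, seed = 9)
  r2 <- robustness_run(fx$graph, det, repeats = 6, fraction = 0.05,
                       min_size = 30, seed = 9)
  expect_identical(r1$avg_max, r2$avg_max)
  expect_length(r1$avg_max, 6L)
  expect_equal(r1$mean, mean(r1$avg_max), tolerance = 1e-9)
  expect_equal(r1$sd, stats::sd(r1$avg_max), tolerance = 1e-9)
  expect_true(all(r1$avg_max >= 0 & r1$avg_max <= 100))
})

test_that("connectivity-requiring methods survive disconnection", {
  # a fragile fixture: two dense blocks joined by a single cut node;
  # deleting nodes can disconnect the graph, and the spin-glass
  # detector then works on the largest component
  fx <- planted_partition_graph(rep(30, 2), 0.6, 0, seed = 7)
  g <- igraph::add_edges(fx$graph,
                         c("g1", "g31"))
  igraph::E(g)$weight <- rep(1, igraph::ecount(g))
  det <- detector("spinglass")
  rep <- robustness_run(g, det, repeats = 4, fraction = 0.05,
                        min_size = 10, seed = 21)
  expect_length(rep$avg_max, 4L)
  expect_true(all(is.finite(rep$avg_max)))
})
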