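# Toy graphs -----------------------------------------------------------

# two triangles joined by a bridge (1-2-3, 4-5-6, bridge 3-4)
two_triangle_graph <- function() {
  graph_from_edges(c("1", "1", "2", "3", "4", "4", "5"),
                   c("2", "3", "3", "4", "5", "6", "6"))
}

two_triangle_partition <- function() {
  partition(stats::setNames(c("a", "a", "a", "b", "b", "b"),
                            as.character(1:6)))
}

complete_graph <- function(n, prefix = "k") {
  idx <- utils::combn(n, 2)
  graph_from_edges(paste0(prefix, idx[1, ]), paste0(prefix, idx[2, ]))
}

path_graph <- function(labels) {
  graph_from_edges(labels[-length(labels)], labels[-1])
}

cycle_graph <- function(n) {
  graph_from_edges(as.character(seq_len(n)),
                   as.character(c(seq_len(n)[-1], 1)))
}

star_graph4 <- function() {
  graph_from_edges(rep("c", 3), c("a", "b", "d"))
}

# two K4 cliques joined by one bridge edge
barbell_graph <- function() {
  graph_from_edges(
    c("a", "a", "a", "b", "b", "c", "e", "e", "e", "f", "f", "g", "d"),
    c("b", "c", "d", "c", "d", "d", "f", "g", "h", "g", "h", "h", "e")
  )
}

disjoint_triangles_graph <- function() {
  graph_from_edges(c("1", "1", "2", "4", "4", "5"),
                   c("2", "3", "3", "5", "6", "6"))
}

random_connected_graph <- function(n, p, seed, prefix = "v") {
  withr::with_seed(seed, {
    repeat {
      g <- igraph::sample_gnp(n, p)
      if (igraph::is_connected(g)) break
    }
    igraph::V(g)$name <- paste0(prefix, seq_len(n))
    igraph::E(g)$weight <- rep(1, igraph::ecount(g))
    g
  })
}

random_partition <- function(nodes, n_comm, seed) {
  withr::with_seed(seed, {
    labs <- c(seq_len(n_comm),
              sample.int(n_comm, length(nodes) - n_comm, replace = TRUE))
    partition(stats::setNames(as.character(sample(labs)), nodes))
  })
}

# Independent oracles ---------------------------------------------------

# every set partition of n items as an integer membership vector
# (restricted growth strings)
all_set_partitions <- function(n) {
  out <- list()
  rec <- function(memb, i, mx) {
    if (i > n) {
      out[[length(out) + 1L]] <<- memb
      return(invisible())
    }
    for (lab in seq_len(mx + 1L)) {
      memb[i] <- lab
      rec(memb, i + 1L, max(mx, lab))
    }
  }
  rec(integer(n), 1L, 0L)
  out
}

# naive double-loop modularity, independent of the package's
# community-form evaluation
naive_modularity <- function(g, memb) {
  A <- as.matrix(igraph::as_adjacency_matrix(g, attr = "weight",
                                             sparse = FALSE))
  k <- rowSums(A)
  m <- sum(A) / 2
  if (m == 0) {
    return(0)
  }
  sum((A - outer(k, k) / (2 * m)) * outer(memb, memb, "==")) / (2 * m)
}

naive_modularity_p <- function(g, p) {
  labs <- p$membership[igraph::V(g)$name]
  naive_modularity(g, as.integer(factor(labs, levels = unique(labs))))
}

# brute-force maximum modularity over every partition (n <= ~9)
brute_force_best <- function(g) {
  n <- igraph::vcount(g)
  A <- as.matrix(igraph::as_adjacency_matrix(g, attr = "weight",
                                             sparse = FALSE))
  k <- rowSums(A)
  m <- sum(A) / 2
  best_q <- -Inf
  best_memb <- NULL
  for (memb in all_set_partitions(n)) {
    q <- if (m == 0) 0 else
      sum((A - outer(k, k) / (2 * m)) * outer(memb, memb, "==")) / (2 * m)
    if (q > best_q) {
      best_q <- q
      best_memb <- memb
    }
  }
  list(q = best_q, memb = best_memb)
}

# naive ordered-pair Hamiltonian, double loop over the energy terms
naive_hamiltonian <- function(g, p, gamma) {
  A <- unname(as.matrix(igraph::as_adjacency_matrix(g, attr = "weight",
                                                    sparse = FALSE)))
  k <- unname(rowSums(A))
  m <- sum(A) / 2
  labs <- unname(p$membership[igraph::V(g)$name])
  n <- length(labs)
  h <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && labs[i] == labs[j]) {
        h <- h - (A[i, j] - gamma * k[i] * k[j] / (2 * m))
      }
    }
  }
  h
}

# pairwise enumeration of the Rand agreement counts (N <= 12)
naive_pair_counts <- function(pa, pb) {
  nodes <- names(pa$membership)
  la <- pa$membership[nodes]
  lb <- pb$membership[nodes]
  n11 <- n00 <- n01 <- n10 <- 0
  N <- length(nodes)
  for (i in seq_len(N - 1)) {
    for (j in seq(i + 1, N)) {
      sa <- la[i] == la[j]
      sb <- lb[i] == lb[j]
      if (sa && sb) n11 <- n11 + 1
      else if (!sa && !sb) n00 <- n00 + 1
      else if (sa) n01 <- n01 + 1
      else n10 <- n10 + 1
    }
  }
  c(n11 = n11, n00 = n00, n01 = n01, n10 = n10)
}

# exact hypergeometric upper tail by direct combinatorial summation
exact_hyper_tail <- function(s, b, k, N) {
  js <- seq(s, min(b, k))
  sum(choose(b, js) * choose(N - b, k - js)) / choose(N, k)
}

# the fixture set for the optimality property: connected graphs with
# at most 10 nodes covering cliques, stars, cycles, bridged cliques
# and random structure
optimality_fixture_set <- function() {
  list(
    two_triangle = two_triangle_graph(),
    k4 = complete_graph(4),
    k5 = complete_graph(5),
    star4 = star_graph4(),
    cycle7 = cycle_graph(7),
    barbell = barbell_graph(),
    rand8a = random_connected_graph(8, 0.35, seed = 2),
    rand8b = random_connected_graph(8, 0.35, seed = 13),
    rand7 = random_connected_graph(7, 0.4, seed = 5, prefix = "u")
  )
}

# canonical form of a partition's blocks for label-free comparison
blocks_sorted <- function(p) {
  bl <- lapply(partition_blocks(p), sort)
  unname(bl[order(vapply(bl, `[`, character(1), 1L))])
}
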