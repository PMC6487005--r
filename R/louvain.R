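#' Louvain two-phase modularity maximization
#'
#' Phase 1 starts from singleton communities and repeatedly sweeps the
#' nodes in a seed-shuffled order, moving each node into the
#' neighboring community with the largest strictly positive modularity
#' gain until a full sweep applies no move. The applied gain is the
#' exact modularity difference of the move,
#' \deqn{\Delta Q = (l_{i,B} - l_{i,A\setminus i})/m -
#'   k_i (K_B - K_{A\setminus i}) / (2 m^2)}
#' with \eqn{l_{i,C}} the weight from node i to community C, \eqn{K_C}
#' the community degree sum and m the total edge weight. Phase 2
#' aggregates each community into a single node of a weighted
#' super-graph (intra-community edges become self-loops) and phase 1 is
#' re-applied. One phase-1/phase-2 cycle is a pass; passes repeat until
#' a pass improves Q by less than `min_gain`.
#'
#' @param g An undirected simple graph (weights honoured).
#' @param seed Integer seed controlling the node visit order.
#' @param min_gain Minimum per-pass modularity improvement to continue
#'   (default 1e-7).
#' @return A [partition()] of the nodes of `g`.
#' @export
louvain <- function(g, seed = 0L, min_gain = 1e-7) {
  gi <- graph_index(g)
  n <- gi$n
  if (n == 0L) {
    return(partition(stats::setNames(character(0), character(0))))
  }
  if (gi$m == 0) {
    return(partition_from_membership(g, seq_len(n)))
  }
  with_seed(seed, {
    lev <- list(n = n, edges = gi$edges, w = gi$edge_w)
    node_comm <- seq_len(n)
    m_tot <- gi$m
    q_prev <- level_modularity(lev, seq_len(lev$n), m_tot)
    repeat {
      ph <- louvain_phase1(lev, m_tot)
      q_new <- level_modularity(lev, ph$memb, m_tot)
      node_comm <- compact_labels(ph$memb[node_comm])
      if (!ph$moved || q_new - q_prev < min_gain) break
      q_prev <- q_new
      lev <- aggregate_level(lev, ph$memb)
      if (lev$n <= 1L) break
    }
    partition_from_membership(g, node_comm)
  })
}

compact_labels <- function(memb) {
  as.integer(factor(memb, levels = unique(memb)))
}

# Modularity of a membership over a level graph (self-loops allowed).
level_modularity <- function(lev, memb, m_tot) {
  k <- level_strength(lev)
  cf <- memb[lev$edges[, 1L]]
  ct <- memb[lev$edges[, 2L]]
  intra <- cf == ct
  e_c <- if (any(intra)) {
    tapply(lev$w[intra], cf[intra], sum)
  } else {
    numeric(0)
  }
  K_c <- tapply(k, memb, sum)
  sum(e_c) / m_tot - sum((K_c / (2 * m_tot))^2)
}

level_strength <- function(lev) {
  k <- numeric(lev$n)
  f <- lev$edges[, 1L]; t <- lev$edges[, 2L]
  for (e in seq_along(lev$w)) {
    if (f[e] == t[e]) {
      k[f[e]] <- k[f[e]] + 2 * lev$w[e]
    } else {
      k[f[e]] <- k[f[e]] + lev$w[e]
      k[t[e]] <- k[t[e]] + lev$w[e]
    }
  }
  k
}

# Phase 1 local-move sweeps on one level graph. Returns the level
# membership, whether any move was applied, and (optionally) the move
# log for consistency checks.
louvain_phase1 <- function(lev, m_tot, record = FALSE) {
  n <- lev$n
  # adjacency excluding self-loops; self-loop weight tracked separately
  adj <- vector("list", n)
  adj_w <- vector("list", n)
  self_w <- numeric(n)
  for (i in seq_len(n)) {
    adj[[i]] <- integer(0)
    adj_w[[i]] <- numeric(0)
  }
  f <- lev$edges[, 1L]; t <- lev$edges[, 2L]
  for (e in seq_along(lev$w)) {
    if (f[e] == t[e]) {
      self_w[f[e]] <- self_w[f[e]] + lev$w[e]
    } else {
      adj[[f[e]]] <- c(adj[[f[e]]], t[e])
      adj_w[[f[e]]] <- c(adj_w[[f[e]]], lev$w[e])
      adj[[t[e]]] <- c(adj[[t[e]]], f[e])
      adj_w[[t[e]]] <- c(adj_w[[t[e]]], lev$w[e])
    }
  }
  k <- vapply(seq_len(n), function(i) sum(adj_w[[i]]), numeric(1)) +
    2 * self_w
  memb <- seq_len(n)
  K <- k
  visit <- if (n > 1L) sample.int(n) else 1L
  moves <- list()
  moved_any <- FALSE
  repeat {
    moved <- FALSE
    for (i in visit) {
      nb <- adj[[i]]
      if (length(nb) == 0L) next
      a <- memb[i]
      lc <- rowsum(adj_w[[i]], memb[nb])
      comms <- as.integer(rownames(lc))
      l_ia <- if (a %in% comms) lc[comms == a, 1L] else 0
      cand <- comms[comms != a]
      if (length(cand) == 0L) next
      l_ib <- lc[match(cand, comms), 1L]
      gain <- (l_ib - l_ia) / m_tot -
        k[i] * (K[cand] - (K[a] - k[i])) / (2 * m_tot^2)
      bi <- which.max(gain)
      if (gain[bi] > 0) {
        b <- cand[bi]
        if (record) {
          moves[[length(moves) + 1L]] <-
            list(node = i, from = a, to = b, gain = unname(gain[bi]))
        }
        K[a] <- K[a] - k[i]
        K[b] <- K[b] + k[i]
        memb[i] <- b
        moved <- TRUE
        moved_any <- TRUE
      }
    }
    if (!moved) break
  }
  list(memb = compact_labels(memb), moved = moved_any, moves = moves)
}

# Build the phase-2 super-graph: one node per community, aggregated
# edge weights, intra-community weight as self-loops.
aggregate_level <- function(lev, memb) {
  nc <- max(memb)
  cf <- memb[lev$edges[, 1L]]
  ct <- memb[lev$edges[, 2L]]
  a <- pmin(cf, ct)
  b <- pmax(cf, ct)
  key <- a + (b - 1) * nc
  agg <- rowsum(lev$w, key)
  keys <- as.numeric(rownames(agg))
  na <- as.integer((keys - 1) %% nc + 1)
  nb <- as.integer((keys - 1) %/% nc + 1)
  list(n = nc, edges = cbind(na, nb), w = agg[, 1L])
}
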