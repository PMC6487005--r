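#' Combo community detection (merge / split / shift search)
#'
#' Starting from a single community, repeatedly considers every
#' (source, destination) community pair - the destination may be an
#' existing community or a new empty one - and evaluates the best
#' repartition of the source's nodes between the two, found by series
#' of Kernighan-Lin node switches started from three kinds of initial
#' configurations: the original communities, the full merger of the
#' source into the destination, and `n_intermediate` random
#' intermediate mergers (a random subset of the source shifted to the
#' destination). Each Kernighan-Lin series switches, among the source
#' nodes not yet moved in this series, the node with the largest
#' (possibly negative) exact modularity gain, and keeps the best
#' prefix. The single best-scoring change over all pairs is applied;
#' the search stops when no change increases modularity. Merges,
#' splits and shifts are all expressible in this move set.
#'
#' @param g An undirected simple graph.
#' @param seed Integer seed (random intermediate configurations).
#' @param max_communities Cap on the number of communities
#'   (default unlimited).
#' @param n_intermediate Random intermediate starting configurations
#'   per pair (default 2).
#' @return A [partition()] of the nodes of `g`.
#' @export
combo <- function(g, seed = 0L, max_communities = Inf,
                  n_intermediate = 2L) {
  gi <- graph_index(g)
  n <- gi$n
  if (n == 0L) {
    return(partition(stats::setNames(character(0), character(0))))
  }
  if (gi$m == 0) {
    return(partition_from_membership(g, rep(1L, n)))
  }
  with_seed(seed, {
    memb <- rep(1L, n)
    repeat {
      comms <- sort(unique(memb))
      best <- list(gain = 1e-12)
      for (s in comms) {
        dests <- c(setdiff(comms, s),
                   if (length(comms) < max_communities) 0L)
        for (d in dests) {
          res <- combo_pair_best(gi, memb, s, d, n_intermediate)
          if (res$gain > best$gain) {
            best <- c(res, list(s = s, d = d))
          }
        }
      }
      if (is.null(best$side)) break
      nodes_s <- which(memb == best$s)
      d_label <- if (best$d == 0L) max(memb) + 1L else best$d
      memb[nodes_s[best$side]] <- d_label
      memb <- compact_labels(memb)
    }
    partition_from_membership(g, memb)
  })
}

# Best repartition of source community s against destination d
# (0 = new empty community): Kernighan-Lin shift series from the
# original, fully-merged and random intermediate configurations.
# Returns the best gain over the original membership and the side
# vector (TRUE = node of s moved to d).
combo_pair_best <- function(gi, memb, s, d, n_intermediate) {
  nodes_s <- which(memb == s)
  ns <- length(nodes_s)
  if (ns == 0L) {
    return(list(gain = 0, side = NULL))
  }
  starts <- list(rep(FALSE, ns), rep(TRUE, ns))
  for (r in seq_len(n_intermediate)) {
    starts[[length(starts) + 1L]] <- stats::runif(ns) < 0.5
  }
  best_gain <- 0
  best_side <- NULL
  for (st in starts) {
    res <- combo_kl_series(gi, memb, s, d, nodes_s, st)
    if (res$gain > best_gain + 1e-12) {
      best_gain <- res$gain
      best_side <- res$side
    }
  }
  list(gain = best_gain, side = best_side)
}

# One Kernighan-Lin refinement: reach `start_side` from the original
# configuration (accumulating exact gains), then switch every source
# node at most once, best (possibly negative) gain first, and return
# the best configuration seen along the series.
combo_kl_series <- function(gi, memb, s, d, nodes_s, start_side) {
  ns <- length(nodes_s)
  m <- gi$m
  pos <- integer(max(gi$n, 1L))
  pos[nodes_s] <- seq_len(ns)
  k <- gi$deg[nodes_s]
  # links from each source node to current s-side and d-side members
  lis <- numeric(ns)
  lid <- numeric(ns)
  for (t in seq_len(ns)) {
    i <- nodes_s[t]
    nb <- gi$adj[[i]]
    w <- gi$adj_w[[i]]
    lis[t] <- sum(w[memb[nb] == s])
    lid[t] <- if (d == 0L) 0 else sum(w[memb[nb] == d])
  }
  Ks <- sum(gi$deg[memb == s])
  Kd <- if (d == 0L) 0 else sum(gi$deg[memb == d])
  side <- rep(FALSE, ns)
  cum <- 0

  switch_node <- function(t) {
    i <- nodes_s[t]
    g_t <- if (!side[t]) {
      (lid[t] - lis[t]) / m - k[t] * (Kd - (Ks - k[t])) / (2 * m^2)
    } else {
      (lis[t] - lid[t]) / m - k[t] * (Ks - (Kd - k[t])) / (2 * m^2)
    }
    dir <- if (!side[t]) 1 else -1
    Ks <<- Ks - dir * k[t]
    Kd <<- Kd + dir * k[t]
    side[t] <<- !side[t]
    nb <- gi$adj[[i]]
    w <- gi$adj_w[[i]]
    inside <- pos[nb] > 0L
    if (any(inside)) {
      tt <- pos[nb[inside]]
      lis[tt] <<- lis[tt] - dir * w[inside]
      lid[tt] <<- lid[tt] + dir * w[inside]
    }
    cum <<- cum + g_t
  }

  for (t in which(start_side)) {
    switch_node(t)
  }
  best_gain <- cum
  best_side <- side
  avail <- rep(TRUE, ns)
  for (step in seq_len(ns)) {
    idx <- which(avail)
    g_stay <- (lid[idx] - lis[idx]) / m -
      k[idx] * (Kd - (Ks - k[idx])) / (2 * m^2)
    g_back <- (lis[idx] - lid[idx]) / m -
      k[idx] * (Ks - (Kd - k[idx])) / (2 * m^2)
    gains <- ifelse(!side[idx], g_stay, g_back)
    pick <- idx[which.max(gains)]
    switch_node(pick)
    avail[pick] <- FALSE
    if (cum > best_gain + 1e-14) {
      best_gain <- cum
      best_side <- side
    }
  }
  list(gain = best_gain, side = best_side)
}
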