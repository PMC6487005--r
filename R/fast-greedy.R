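#' Fast greedy agglomerative community detection (CNM)
#'
#' Starts from singleton communities and repeatedly merges the pair of
#' connected communities with the largest modularity gain, maintaining
#' a sparse matrix of pairwise gains \eqn{\Delta Q_{ij}} together with
#' the degree shares \eqn{a_i = k_i / 2m} and the maximum over each
#' row. After merging community i into j the affected entries are
#' updated in place: \eqn{\Delta Q'_{jk} = \Delta Q_{ik} + \Delta
#' Q_{jk}} when k is connected to both, \eqn{\Delta Q_{ik} - 2 a_j
#' a_k} when connected to i only, and \eqn{\Delta Q_{jk} - 2 a_i a_k}
#' when connected to j only, with \eqn{a'_j = a_j + a_i}. Stored gains
#' equal the exact modularity difference of performing the merge, so
#' the recorded Q trajectory is exact. Once no connected pair remains
#' (one community per component), remaining components are merged in
#' order of least modularity loss until a single community remains.
#'
#' @param g An undirected simple graph.
#' @return A [community_dendrogram]; its [best_cut()] is the partition
#'   of maximal recorded modularity.
#' @export
fast_greedy <- function(g) {
  gi <- graph_index(g)
  n <- gi$n
  empty_steps <- data.frame(step = integer(0), operation = character(0),
                            detail = character(0), q = numeric(0))
  if (n == 0L) {
    return(new_dendrogram(g, empty_steps, list(), "fast_greedy"))
  }
  st <- fg_state(gi)
  memb <- seq_len(n)
  q_cur <- st$q0
  memberships <- list(memb)
  ops <- list(list(operation = "initial", detail = "", q = q_cur))

  repeat {
    pick <- fg_best_pair(st)
    if (is.null(pick)) {
      # no connected pair left: merge remaining components, least loss
      # (largest -2 a_i a_j) first
      alive <- which(st$alive)
      if (length(alive) <= 1L) break
      ord <- alive[order(st$a[alive])]
      i <- ord[1L]; j <- ord[2L]
      dq <- -2 * st$a[i] * st$a[j]
      st$a[j] <- st$a[j] + st$a[i]
      st$a[i] <- 0
      st$alive[i] <- FALSE
    } else {
      i <- pick$i; j <- pick$j; dq <- pick$dq
      st <- fg_merge(st, i, j)
    }
    q_cur <- q_cur + dq
    memb[memb == i] <- j
    memberships[[length(memberships) + 1L]] <- memb
    ops[[length(ops) + 1L]] <- list(
      operation = "merge", detail = paste0(i, "+", j, "->", j), q = q_cur)
  }
  steps_df <- data.frame(
    step = seq_along(ops),
    operation = vapply(ops, `[[`, character(1), "operation"),
    detail = vapply(ops, `[[`, character(1), "detail"),
    q = vapply(ops, `[[`, numeric(1), "q")
  )
  new_dendrogram(g, steps_df, memberships, "fast_greedy")
}

# Initial gain bookkeeping: sparse rows of exact pairwise merge gains
# for connected communities, degree shares a_i, singleton-partition Q.
fg_state <- function(gi) {
  n <- gi$n
  m <- gi$m
  a <- if (m > 0) gi$deg / (2 * m) else rep(0, n)
  dq <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- gi$adj[[i]]
    w <- gi$adj_w[[i]]
    if (length(nb) > 0L) {
      v <- w / m - 2 * a[i] * a[nb]
      names(v) <- as.character(nb)
      dq[[i]] <- v
    } else {
      dq[[i]] <- stats::setNames(numeric(0), character(0))
    }
  }
  list(dq = dq, a = a, alive = rep(TRUE, n), q0 = -sum(a^2))
}

fg_best_pair <- function(st) {
  rowmax <- vapply(st$dq, function(v) if (length(v)) max(v) else -Inf,
                   numeric(1))
  rowmax[!st$alive] <- -Inf
  if (all(rowmax == -Inf)) {
    return(NULL)
  }
  i <- which.max(rowmax)
  row <- st$dq[[i]]
  j <- as.integer(names(row)[which.max(row)])
  list(i = i, j = j, dq = rowmax[i])
}

# Merge community i into j, applying the sparse update rules.
fg_merge <- function(st, i, j) {
  row_i <- st$dq[[i]]
  row_j <- st$dq[[j]]
  ks <- union(names(row_i), names(row_j))
  ks <- setdiff(ks, as.character(c(i, j)))
  new_row <- stats::setNames(numeric(length(ks)), ks)
  for (k in ks) {
    in_i <- k %in% names(row_i)
    in_j <- k %in% names(row_j)
    ki <- as.integer(k)
    val <- if (in_i && in_j) {
      row_i[[k]] + row_j[[k]]
    } else if (in_i) {
      row_i[[k]] - 2 * st$a[j] * st$a[ki]
    } else {
      row_j[[k]] - 2 * st$a[i] * st$a[ki]
    }
    new_row[[k]] <- val
    # mirror entry in row k: drop i, set j
    rk <- st$dq[[ki]]
    rk <- rk[setdiff(names(rk), as.character(c(i, j)))]
    rk[[as.character(j)]] <- val
    st$dq[[ki]] <- rk
  }
  st$dq[[j]] <- new_row
  st$dq[[i]] <- stats::setNames(numeric(0), character(0))
  st$a[j] <- st$a[j] + st$a[i]
  st$a[i] <- 0
  st$alive[i] <- FALSE
  st
}
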