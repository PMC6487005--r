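#' Newman-Girvan modularity of a partition
#'
#' Computes
#' \deqn{Q = \frac{1}{2m} \sum_{i,j} \left[A_{ij} - \frac{k_i k_j}{2m}\right]
#'   \delta(c_i, c_j)}
#' summed over all ordered node pairs including \eqn{i = j} (so the
#' single-community partition of any graph scores exactly 0, and every
#' partition of a complete graph scores at most 0). \eqn{A_{ij}} is the
#' edge weight, \eqn{k_i} the weighted degree, \eqn{m} the total edge
#' weight. Evaluated in the equivalent community form
#' \eqn{\sum_c (e_c/m - (d_c/2m)^2)} with \eqn{e_c} the internal edge
#' weight and \eqn{d_c} the total degree of community \eqn{c}.
#'
#' @param g An undirected graph.
#' @param p A [partition()] covering (at least) the nodes of `g`.
#' @return Modularity Q, a number in \eqn{[-1, 1)}.
#' @export
modularity_q <- function(g, p) {
  memb <- membership_for_graph(g, p)
  gi <- graph_index(g)
  modularity_from_index(gi, memb)
}

# Q from the internal graph index and an integer membership vector.
modularity_from_index <- function(gi, memb) {
  if (gi$m == 0) {
    return(0)
  }
  m <- gi$m
  nc <- max(memb)
  # internal weight per community
  c_from <- memb[gi$edges[, 1L]]
  c_to <- memb[gi$edges[, 2L]]
  intra <- c_from == c_to
  e_c <- numeric(nc)
  if (any(intra)) {
    agg <- rowsum(gi$edge_w[intra], c_from[intra])
    e_c[as.integer(rownames(agg))] <- agg[, 1L]
  }
  d_c <- numeric(nc)
  agg_d <- rowsum(gi$deg, memb)
  d_c[as.integer(rownames(agg_d))] <- agg_d[, 1L]
  sum(e_c / m - (d_c / (2 * m))^2)
}

# Sum of degree-share squares Sum_i k_i^2/(2m)^2: the partition-
# independent diagonal term relating Q to the spin-glass Hamiltonian.
diagonal_constant <- function(g) {
  gi <- graph_index(g)
  if (gi$m == 0) {
    return(0)
  }
  sum(gi$deg^2) / (2 * gi$m)^2
}
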