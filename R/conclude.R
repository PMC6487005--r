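#' Kappa-path edge centrality by random simple-path sampling
#'
#' Estimates, for every edge, the probability that a random simple path
#' of length at most `kappa` traverses it: `phi` paths are simulated,
#' each starting from a uniformly chosen source node and extending
#' uniformly among not-yet-visited neighbors until no unvisited
#' neighbor remains or `kappa` steps were taken; traversal counts are
#' normalized by the number of simulated paths.
#'
#' @param g A connected undirected simple graph.
#' @param kappa Maximum path length (>= 1), default 20.
#' @param phi Number of simulated paths; default `10 * m`.
#' @param seed Integer seed.
#' @return Numeric vector of centrality estimates, one per edge of `g`
#'   (in `igraph::E(g)` order).
#' @export
kpath_edge_centrality <- function(g, kappa = 20L, phi = NULL, seed = 0L) {
  if (kappa < 1L) {
    stop("kappa must be at least 1")
  }
  gi <- graph_index(g)
  n <- gi$n
  n_edges <- nrow(gi$edges)
  if (n_edges == 0L) {
    return(numeric(0))
  }
  if (is.null(phi)) {
    phi <- 10L * n_edges
  }
  # edge index lookup for each adjacency slot
  eid <- edge_ids_for_adjacency(gi)
  counts <- numeric(n_edges)
  with_seed(seed, {
    sources <- sample.int(n, phi, replace = TRUE)
    for (p in seq_len(phi)) {
      v <- sources[p]
      visited <- integer(0)
      for (step in seq_len(kappa)) {
        visited <- c(visited, v)
        nb <- gi$adj[[v]]
        open <- !(nb %in% visited)
        if (!any(open)) break
        slot <- which(open)
        pick <- slot[sample.int(length(slot), 1L)]
        counts[eid[[v]][pick]] <- counts[eid[[v]][pick]] + 1
        v <- nb[pick]
      }
    }
  })
  counts / phi
}

edge_ids_for_adjacency <- function(gi) {
  n_edges <- nrow(gi$edges)
  ids <- c(seq_len(n_edges), seq_len(n_edges))
  from <- c(gi$edges[, 1L], gi$edges[, 2L])
  to <- c(gi$edges[, 2L], gi$edges[, 1L])
  ord <- order(from)
  from <- from[ord]; to <- to[ord]; ids <- ids[ord]
  eid <- vector("list", gi$n)
  runs <- split(seq_along(from), factor(from, levels = seq_len(gi$n)))
  for (i in seq_len(gi$n)) {
    idx <- runs[[i]]
    # align with gi$adj[[i]] ordering (simple graph: neighbors unique)
    eid[[i]] <- ids[idx][match(gi$adj[[i]], to[idx])]
  }
  eid
}

#' Centrality-weighted distance between the endpoints of an edge
#'
#' The dissimilarity used by the CONCLUDE variant: for adjacent nodes i
#' and j with neighbor sets N(i), N(j) and common neighbors CN(i,j),
#' \deqn{\sigma_{ij} = \sqrt{
#'  \frac{\sum_{k \in N(i) \setminus CN} L(e_{ki})^2}{|N(i) \setminus CN|} +
#'  \frac{\sum_{k \in N(j) \setminus CN} L(e_{kj})^2}{|N(j) \setminus CN|} +
#'  \frac{\sum_{k \in CN} (L(e_{ki}) - L(e_{kj}))^2}{|CN|}}}
#' where L are the kappa-path edge centralities. Each node's own
#' partner is excluded from its neighbor set, and a term with an empty
#' index set contributes zero.
#'
#' @param g The graph.
#' @param centrality Edge centralities in `igraph::E(g)` order.
#' @return Numeric vector of distances, one per edge of `g`.
#' @export
endpoint_distances <- function(g, centrality) {
  gi <- graph_index(g)
  n_edges <- nrow(gi$edges)
  if (length(centrality) != n_edges) {
    stop("need one centrality value per edge")
  }
  eid <- edge_ids_for_adjacency(gi)
  sigma <- numeric(n_edges)
  for (e in seq_len(n_edges)) {
    i <- gi$edges[e, 1L]
    j <- gi$edges[e, 2L]
    sigma[e] <- sigma_pair(gi, eid, centrality, i, j)
  }
  sigma
}

sigma_pair <- function(gi, eid, centrality, i, j) {
  ni <- setdiff(gi$adj[[i]], j)
  nj <- setdiff(gi$adj[[j]], i)
  cn <- intersect(ni, nj)
  li <- centrality[eid[[i]][match(setdiff(ni, cn), gi$adj[[i]])]]
  lj <- centrality[eid[[j]][match(setdiff(nj, cn), gi$adj[[j]])]]
  lci <- centrality[eid[[i]][match(cn, gi$adj[[i]])]]
  lcj <- centrality[eid[[j]][match(cn, gi$adj[[j]])]]
  term <- function(x) if (length(x) == 0L) 0 else sum(x^2) / length(x)
  sqrt(term(li) + term(lj) +
         (if (length(cn) == 0L) 0 else sum((lci - lcj)^2) / length(cn)))
}

#' CONCLUDE-style community detection
#'
#' Three stages: (1) estimate kappa-path edge centralities by sampled
#' random simple paths ([kpath_edge_centrality()]); (2) convert the
#' centralities into endpoint distances sigma_ij for every edge
#' ([endpoint_distances()]); (3) run [louvain()] on the network
#' reweighted by the similarity `w_ij = 1 / (1 + sigma_ij)`, so edges
#' whose endpoints look alike in centrality space weigh more. The
#' similarity transform is this package's reading of "cluster on the
#' distance matrix"; it is monotone decreasing in the distance and
#' keeps weights in (0, 1].
#'
#' @param g A connected undirected simple graph.
#' @param kappa Maximum sampled path length (>= 1), default 20.
#' @param phi Number of sampled paths, default `10 * m`.
#' @param seed Integer seed (sampling and Louvain sweep order).
#' @return A [partition()] of the nodes of `g`.
#' @export
conclude <- function(g, kappa = 20L, phi = NULL, seed = 0L) {
  if (!is_connected_graph(g)) {
    stop("conclude requires a connected graph; run per component")
  }
  if (kappa < 1L) {
    stop("kappa must be at least 1")
  }
  if (igraph::ecount(g) == 0L) {
    return(partition(stats::setNames(rep("1", igraph::vcount(g)),
                                     igraph::V(g)$name)))
  }
  centr <- kpath_edge_centrality(g, kappa = kappa, phi = phi, seed = seed)
  sigma <- endpoint_distances(g, centr)
  gw <- igraph::set_edge_attr(g, "weight", value = 1 / (1 + sigma))
  louvain(gw, seed = derive_seed(seed, 1L))
}
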