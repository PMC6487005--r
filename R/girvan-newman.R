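#' Girvan-Newman divisive community detection
#'
#' Iteratively removes the edge of maximal shortest-path edge
#' betweenness, recomputing betweenness over the remaining edges after
#' every removal, and records the component structure each time a
#' removal changes it. The recorded sequence of partitions forms a
#' dendrogram; the division of maximal modularity is the suggested
#' cut. Ties in maximal betweenness are broken by lexicographic edge
#' order (smaller endpoint pair first) so the procedure is
#' deterministic. Complexity is O(m^2 n); intended for small networks.
#'
#' @param g An undirected simple graph.
#' @return A [community_dendrogram] whose steps run from the initial
#'   component partition down to all-singletons.
#' @export
girvan_newman <- function(g) {
  n <- igraph::vcount(g)
  if (n == 0L) {
    return(new_dendrogram(g, data.frame(step = integer(0),
                                        operation = character(0),
                                        detail = character(0),
                                        q = numeric(0)),
                          list(), "girvan_newman"))
  }
  gi0 <- graph_index(g)
  work <- g
  memb <- component_membership(work)
  steps <- list(list(operation = "initial", detail = "", q = NA_real_))
  memberships <- list(memb)
  removed <- 0L
  while (igraph::ecount(work) > 0L) {
    eb <- igraph::edge_betweenness(work, directed = FALSE)
    ends <- igraph::as_edgelist(work, names = TRUE)
    # deterministic tie-break: lexicographic on canonical endpoint pair
    a <- pmin(ends[, 1L], ends[, 2L])
    b <- pmax(ends[, 1L], ends[, 2L])
    ord <- order(-eb, a, b)
    pick <- ord[1L]
    work <- igraph::delete_edges(work, pick)
    removed <- removed + 1L
    new_memb <- component_membership(work)
    if (max(new_memb) > max(memb)) {
      memb <- new_memb
      steps[[length(steps) + 1L]] <- list(
        operation = "split",
        detail = paste0(a[pick], "--", b[pick]),
        q = NA_real_
      )
      memberships[[length(memberships) + 1L]] <- memb
    }
  }
  q <- vapply(memberships, function(mm) modularity_from_index(gi0, mm),
              numeric(1))
  steps_df <- data.frame(
    step = seq_along(steps),
    operation = vapply(steps, `[[`, character(1), "operation"),
    detail = vapply(steps, `[[`, character(1), "detail"),
    q = q
  )
  new_dendrogram(g, steps_df, memberships, "girvan_newman")
}

component_membership <- function(g) {
  as.integer(igraph::components(g)$membership)
}
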