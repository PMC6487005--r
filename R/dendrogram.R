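#' @title Dendrograms from divisive / agglomerative detection
#' @description Divisive (edge-removal) and agglomerative (merge)
#' algorithms record the full sequence of partitions they traverse with
#' the modularity of each step; the best cut is the recorded partition
#' of maximal Q (earliest step on ties).
#' @name community_dendrogram
NULL

# steps: data.frame(step, operation, detail, q)
# memberships: list of integer membership vectors (graph vertex order)
new_dendrogram <- function(g, steps, memberships, method) {
  stopifnot(nrow(steps) == length(memberships))
  structure(
    list(graph = g, steps = steps, memberships = memberships,
         method = method),
    class = "community_dendrogram"
  )
}

#' @export
print.community_dendrogram <- function(x, ...) {
  cat("Community dendrogram (", x$method, "): ", nrow(x$steps),
      " recorded steps, best Q = ", format(max(x$steps$q), digits = 6),
      "\n", sep = "")
  invisible(x)
}

#' Best modularity cut of a dendrogram
#'
#' @param d A `community_dendrogram`.
#' @return A list with `partition` (the [partition()] of maximal
#'   recorded Q, ties to the earliest step) and `q`.
#' @export
best_cut <- function(d) {
  stopifnot(inherits(d, "community_dendrogram"))
  if (nrow(d$steps) == 0L) {
    return(list(partition = partition(stats::setNames(character(0), character(0))),
                q = 0))
  }
  i <- which.max(d$steps$q)
  list(partition = partition_from_membership(d$graph, d$memberships[[i]]),
       q = d$steps$q[i])
}

#' All recorded modularity values of a dendrogram
#' @param d A `community_dendrogram`.
#' @return Numeric vector of Q values, one per recorded step.
#' @export
dendrogram_q <- function(d) d$steps$q

#' Recorded partition at a given dendrogram step
#' @param d A `community_dendrogram`.
#' @param step Step index (1-based).
#' @return A [partition()].
#' @export
dendrogram_partition <- function(d, step) {
  partition_from_membership(d$graph, d$memberships[[step]])
}
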