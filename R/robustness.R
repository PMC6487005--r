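#' Randomly delete a fraction of nodes from a graph
#'
#' Removes exactly `round(fraction * n)` distinct nodes chosen
#' uniformly at random (seeded) together with their incident edges.
#'
#' @param g The graph.
#' @param fraction Fraction of nodes to remove, in `(0, 1]` (a fraction
#'   rounding to 0 returns the graph unchanged; rounding to n is an
#'   error).
#' @param seed Integer seed.
#' @return A list with `graph` (the perturbed graph) and `removed`
#'   (character vector of deleted node names).
#' @export
perturb_graph <- function(g, fraction, seed = 1L) {
  n <- igraph::vcount(g)
  if (n == 0L) {
    stop("cannot perturb an empty graph")
  }
  n_remove <- round(fraction * n)
  if (n_remove >= n) {
    stop("fraction would remove every node")
  }
  if (n_remove == 0L) {
    return(list(graph = g, removed = character(0)))
  }
  removed <- with_seed(seed, sample(igraph::V(g)$name, n_remove))
  list(
    graph = igraph::delete_vertices(g, removed),
    removed = removed
  )
}

#' Drop removed nodes from a reference partition
#'
#' @param p A [partition()].
#' @param removed Character vector of node names to drop.
#' @return A [partition()] without the removed nodes; emptied blocks
#'   disappear.
#' @export
restrict_partition <- function(p, removed) {
  stopifnot(inherits(p, "node_partition"))
  keep <- !(names(p$membership) %in% removed)
  partition(p$membership[keep])
}

#' Average column-wise maximum Jaccard between two partitions
#'
#' Builds the [jaccard_matrix()] over communities with at least
#' `min_size` nodes, takes the maximum of every column and returns the
#' mean of those maxima (a percentage). In the robustness pipeline the
#' first argument is the perturbed-network partition (rows) and the
#' second the restricted reference partition (columns), so the
#' statistic asks how well each reference community is recovered after
#' perturbation. The statistic is not symmetric in its arguments.
#'
#' @param pa Row partition (perturbed-network communities).
#' @param pb Column partition (restricted reference communities).
#' @param min_size Minimum community size (default 100).
#' @return A percentage in `[0, 100]`.
#' @export
avg_max_jaccard <- function(pa, pb, min_size = 100L) {
  jm <- jaccard_matrix(pa, pb, min_size)
  if (nrow(jm) == 0L || ncol(jm) == 0L) {
    stop("no community of size >= ", min_size,
         " in one of the partitions; avg-max Jaccard undefined")
  }
  mean(apply(jm, 2L, max))
}

#' Node-deletion robustness of a detection method
#'
#' Quantifies how stable a method's communities are under small random
#' perturbations of the network. The reference partition is computed
#' once on the full graph. Then, per repeat: (1) remove
#' `round(fraction * n)` random nodes, (2) re-detect communities on
#' the perturbed graph, (3) drop the removed nodes from the reference
#' partition, (4-6) compute the [avg_max_jaccard()] between the
#' perturbed-run partition and the restricted reference over
#' communities with at least `min_size` nodes. Per-repeat seeds derive
#' deterministically from the master seed. If a connectivity-requiring
#' method was restricted to the largest component of the perturbed
#' graph, the nodes outside that component are treated like deleted
#' nodes for that repeat (recorded in `dropped_extra`).
#'
#' @param g The graph.
#' @param method A detector closure from [detector()].
#' @param repeats Number of perturbation repeats (default 100).
#' @param fraction Fraction of nodes removed per repeat (default 0.01).
#' @param min_size Minimum community size in the Jaccard step
#'   (default 100).
#' @param seed Master seed.
#' @return A list of class `robustness_report`: `avg_max` (one value
#'   per repeat, percent), `mean`, `sd` (sample sd, n-1),
#'   `dropped_extra` (per-repeat count of nodes lost to
#'   disconnection), `parameters`.
#' @export
robustness_run <- function(g, method, repeats = 100L, fraction = 0.01,
                           min_size = 100L, seed = 1L) {
  reference <- method(g, seed)
  avg_max <- numeric(repeats)
  dropped_extra <- integer(repeats)
  for (r in seq_len(repeats)) {
    rs <- derive_seed(seed, r)
    pert <- perturb_graph(g, fraction, seed = rs)
    p_pert <- method(pert$graph, rs)
    # method may have shed further nodes (e.g. restricted to the
    # largest component): treat them like deleted nodes
    lost <- setdiff(igraph::V(pert$graph)$name, names(p_pert$membership))
    dropped_extra[r] <- length(lost)
    ref_r <- restrict_partition(reference, c(pert$removed, lost))
    avg_max[r] <- avg_max_jaccard(p_pert, ref_r, min_size)
  }
  structure(
    list(
      avg_max = avg_max,
      mean = mean(avg_max),
      sd = if (repeats > 1L) stats::sd(avg_max) else 0,
      dropped_extra = dropped_extra,
      parameters = list(method = attr(method, "method"),
                        repeats = repeats, fraction = fraction,
                        min_size = min_size, seed = seed)
    ),
    class = "robustness_report"
  )
}

#' @export
print.robustness_report <- function(x, ...) {
  cat("Robustness (", x$parameters$method, ", ",
      100 * x$parameters$fraction, "% node deletion, ",
      x$parameters$repeats, " repeats): mean avg-max Jaccard ",
      format(x$mean, digits = 4), "%, sd ", format(x$sd, digits = 4),
      "%\n", sep = "")
  invisible(x)
}
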