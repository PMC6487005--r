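#' Construct a partition of network nodes into communities
#'
#' A partition assigns every node exactly one community label; blocks
#' are derived as the label-indexed node sets. Labels are opaque and
#' kept as characters.
#'
#' @param membership A named vector: names are node identifiers, values
#'   community labels.
#' @return An object of class `node_partition`.
#' @export
partition <- function(membership) {
  if (is.null(names(membership)) || anyNA(membership)) {
    stop("membership must be a named vector without NAs")
  }
  if (anyDuplicated(names(membership))) {
    dup <- names(membership)[duplicated(names(membership))][1L]
    stop("node assigned more than once: ", dup)
  }
  m <- stats::setNames(as.character(membership), names(membership))
  structure(list(membership = m), class = "node_partition")
}

#' @export
print.node_partition <- function(x, ...) {
  sizes <- sort(table(x$membership), decreasing = TRUE)
  cat("Partition of", length(x$membership), "nodes into",
      length(sizes), "communities\n")
  cat("block sizes:", paste(utils::head(sizes, 12L), collapse = ", "),
      if (length(sizes) > 12L) "...\n" else "\n")
  invisible(x)
}

#' Blocks (community node sets) of a partition
#'
#' @param p A `node_partition`.
#' @return Named list of character vectors, one per community.
#' @export
partition_blocks <- function(p) {
  stopifnot(inherits(p, "node_partition"))
  split(names(p$membership), p$membership)
}

#' Number of communities in a partition
#' @param p A `node_partition`.
#' @return Integer count of non-empty blocks.
#' @export
n_communities <- function(p) {
  length(unique(p$membership))
}

#' Relabel communities by decreasing size
#'
#' Communities are renamed `1`, `2`, ... from largest to smallest
#' (ties by current label order), the convention used for reporting
#' (largest community first).
#'
#' @param p A `node_partition`.
#' @return A `node_partition` with size-ranked labels.
#' @export
rank_by_size <- function(p) {
  sizes <- table(p$membership)
  ord <- names(sizes)[order(-as.vector(sizes), names(sizes))]
  remap <- stats::setNames(as.character(seq_along(ord)), ord)
  partition(stats::setNames(remap[p$membership], names(p$membership)))
}

#' Read a partition from a two-column TSV (node, community label)
#'
#' Duplicated nodes with identical labels are accepted once; a node
#' listed with two different labels is an error.
#'
#' @param path Path to a headerless two-column tab-separated file.
#' @return A `node_partition`.
#' @export
read_partition <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character", comment.char = "#",
                          quote = "")
  if (ncol(df) < 2L) {
    stop("partition file must have two tab-separated columns")
  }
  df <- unique(df[, 1:2])
  if (anyDuplicated(df[[1L]])) {
    dup <- df[[1L]][duplicated(df[[1L]])][1L]
    stop("node '", dup, "' listed with conflicting community labels")
  }
  partition(stats::setNames(df[[2L]], df[[1L]]))
}

#' Write a partition to a two-column TSV (node, community label)
#'
#' @param p A `node_partition`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(p, path) {
  stopifnot(inherits(p, "node_partition"))
  utils::write.table(
    data.frame(node = names(p$membership), community = p$membership),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

# Integer membership vector aligned with graph vertex order; errors if
# the partition does not cover the graph.
membership_for_graph <- function(g, p) {
  stopifnot(inherits(p, "node_partition"))
  nodes <- igraph::V(g)$name
  missing <- setdiff(nodes, names(p$membership))
  if (length(missing) > 0L) {
    stop("partition does not cover graph node(s): ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  labs <- p$membership[nodes]
  as.integer(factor(labs, levels = unique(labs)))
}

# Partition from an integer membership vector in graph vertex order.
partition_from_membership <- function(g, memb) {
  partition(stats::setNames(as.character(memb), igraph::V(g)$name))
}
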