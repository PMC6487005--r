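#' Read an interaction network from a tab-separated edge list
#'
#' Reads a two-column (or BioGRID-style multi-column) tab-separated edge
#' list of gene identifiers and returns a simple undirected graph:
#' self-loops are dropped and repeated edges (in either orientation)
#' are collapsed to a single edge of weight 1. Node identifiers are
#' treated as opaque, case-sensitive strings. Lines starting with `#`
#' are skipped.
#'
#' @param path Path to a tab-separated text file.
#' @param source_col,target_col 1-based column indices holding the two
#'   interactor identifiers. Defaults to the first two columns.
#' @param has_header Logical; if `TRUE` the first non-comment line is
#'   discarded.
#' @return An undirected [igraph::igraph] graph with vertex attribute
#'   `name` and edge attribute `weight` (all 1).
#' @export
read_edge_list <- function(path, source_col = 1L, target_col = 2L,
                           has_header = FALSE) {
  if (!file.exists(path)) {
    stop("edge list file not found: ", path)
  }
  lines <- readLines(path)
  keep <- !startsWith(lines, "#")
  line_no <- seq_along(lines)[keep]
  lines <- lines[keep]
  if (has_header && length(lines) > 0L) {
    lines <- lines[-1L]
    line_no <- line_no[-1L]
  }
  nonblank <- nzchar(trimws(lines))
  lines <- lines[nonblank]
  line_no <- line_no[nonblank]
  if (length(lines) == 0L) {
    return(empty_graph())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  need <- max(source_col, target_col)
  bad <- which(vapply(fields, length, integer(1)) < need)
  if (length(bad) > 0L) {
    stop("malformed row at line ", line_no[bad[1L]],
         ": expected at least ", need, " tab-separated columns")
  }
  from <- vapply(fields, `[[`, character(1), source_col)
  to <- vapply(fields, `[[`, character(1), target_col)
  graph_from_edges(from, to)
}

#' Build a simple undirected graph from endpoint vectors
#'
#' Duplicate edges (either orientation) collapse to one edge of weight 1
#' and self-loops are discarded; the node set is the union of the two
#' endpoint vectors (so a node appearing only in a dropped self-loop is
#' retained as an isolated node).
#'
#' @param from,to Character vectors of equal length.
#' @param nodes Optional character vector of additional node names.
#' @return An undirected simple [igraph::igraph] graph, `weight` all 1.
#' @export
graph_from_edges <- function(from, to, nodes = character(0)) {
  from <- as.character(from)
  to <- as.character(to)
  stopifnot(length(from) == length(to))
  all_nodes <- unique(c(from, to, as.character(nodes)))
  keep <- from != to
  from <- from[keep]
  to <- to[keep]
  if (length(from) == 0L) {
    g <- igraph::make_empty_graph(length(all_nodes), directed = FALSE)
    igraph::V(g)$name <- all_nodes
    return(igraph::set_edge_attr(g, "weight", value = numeric(0)))
  }
  # canonical orientation so (u,v) and (v,u) collapse together
  a <- pmin(from, to)
  b <- pmax(from, to)
  key <- paste0(a, "\r", b)
  dup <- duplicated(key)
  a <- a[!dup]
  b <- b[!dup]
  g <- igraph::graph_from_data_frame(
    data.frame(from = a, to = b, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = all_nodes, stringsAsFactors = FALSE)
  )
  igraph::E(g)$weight <- rep(1, igraph::ecount(g))
  g
}

empty_graph <- function() {
  g <- igraph::make_empty_graph(0, directed = FALSE)
  igraph::set_edge_attr(g, "weight", value = numeric(0))
}

#' Write a graph back to a two-column tab-separated edge list
#'
#' @param g An undirected graph.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  el <- igraph::as_edgelist(g, names = TRUE)
  utils::write.table(el, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Connected components, largest first
#'
#' @param g An undirected graph.
#' @return A list of character vectors of node names, ordered by
#'   decreasing component size (ties by first occurrence).
#' @export
connected_components <- function(g) {
  if (igraph::vcount(g) == 0L) {
    return(list())
  }
  comp <- igraph::components(g)
  groups <- split(igraph::V(g)$name, comp$membership)
  groups[order(-comp$csize, as.integer(names(groups)))]
}

#' Node degrees and the degree histogram
#'
#' @param g An undirected graph.
#' @return A list with `degree` (named numeric vector, sum of incident
#'   edge weights per node) and `histogram` (a table of node counts per
#'   degree value, for unit-weight graphs the classical degree
#'   distribution).
#' @export
degree_sequence <- function(g) {
  deg <- igraph::strength(g, loops = FALSE)
  names(deg) <- igraph::V(g)$name
  hist <- table(deg)
  list(degree = deg, histogram = hist)
}

largest_component <- function(g) {
  comps <- connected_components(g)
  if (length(comps) <= 1L) {
    return(g)
  }
  igraph::induced_subgraph(g, comps[[1L]])
}

is_connected_graph <- function(g) {
  igraph::vcount(g) == 0L || igraph::is_connected(g)
}

# Internal indexed view of a graph used by the detection algorithms:
# integer node ids, CSR-like adjacency, strengths and total weight.
graph_index <- function(g) {
  n <- igraph::vcount(g)
  names <- igraph::V(g)$name
  if (is.null(names)) {
    names <- as.character(seq_len(n))
  }
  w <- igraph::E(g)$weight
  if (is.null(w)) {
    w <- rep(1, igraph::ecount(g))
  }
  el <- igraph::as_edgelist(g, names = FALSE)
  # adjacency lists: neighbors and parallel weights
  from <- c(el[, 1L], el[, 2L])
  to <- c(el[, 2L], el[, 1L])
  ww <- c(w, w)
  ord <- order(from)
  from <- from[ord]; to <- to[ord]; ww <- ww[ord]
  adj <- vector("list", n)
  adj_w <- vector("list", n)
  if (length(from) > 0L) {
    runs <- split(seq_along(from), factor(from, levels = seq_len(n)))
    for (i in seq_len(n)) {
      idx <- runs[[i]]
      adj[[i]] <- to[idx]
      adj_w[[i]] <- ww[idx]
    }
  } else {
    for (i in seq_len(n)) {
      adj[[i]] <- integer(0)
      adj_w[[i]] <- numeric(0)
    }
  }
  deg <- vapply(adj_w, sum, numeric(1))
  list(
    n = n, names = names, m = sum(w),
    edges = el, edge_w = w,
    adj = adj, adj_w = adj_w, deg = deg
  )
}
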