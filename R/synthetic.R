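#' Planted-partition benchmark graph
#'
#' Generates an undirected simple graph with known ground-truth blocks:
#' each within-block node pair is connected independently with
#' probability `p_in` and each between-block pair with probability
#' `p_out`. With `heterogeneous = TRUE`, per-node propensities drawn
#' from a lognormal distribution (sigma = 1, normalized to mean 1)
#' multiply into the pair probabilities (clipped at 1), producing the
#' right-skewed degree distributions characteristic of protein
#' interaction networks while keeping the expected edge count
#' approximately unchanged. Self-loops are never produced; isolated
#' nodes are retained. Ground-truth labels are integers 1..B.
#'
#' @param sizes Integer vector of block sizes (each >= 1).
#' @param p_in,p_out Within- and between-block edge probabilities,
#'   `0 <= p_out < p_in <= 1`.
#' @param seed Integer seed.
#' @param heterogeneous Add lognormal degree heterogeneity
#'   (default `FALSE`).
#' @return A list of class `planted_fixture`: `graph` (igraph),
#'   `truth` (a [partition()]) and `parameters`.
#' @export
planted_partition_graph <- function(sizes, p_in, p_out, seed = 1L,
                                    heterogeneous = FALSE) {
  stopifnot(all(sizes >= 1), p_out >= 0, p_in <= 1)
  if (!(p_out < p_in)) {
    stop("need p_out < p_in")
  }
  n <- sum(sizes)
  block <- rep(seq_along(sizes), sizes)
  nodes <- paste0("g", seq_len(n))
  with_seed(seed, {
    theta <- if (heterogeneous) {
      th <- stats::rlnorm(n, meanlog = 0, sdlog = 1)
      th / mean(th)
    } else {
      rep(1, n)
    }
    pair <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    i <- pair[, 1L]
    j <- pair[, 2L]
    base <- ifelse(block[i] == block[j], p_in, p_out)
    prob <- pmin(base * theta[i] * theta[j], 1)
    keep <- stats::runif(length(prob)) < prob
    g <- graph_from_edges(nodes[i[keep]], nodes[j[keep]], nodes = nodes)
    structure(
      list(
        graph = g,
        truth = partition(stats::setNames(as.character(block), nodes)),
        parameters = list(sizes = sizes, p_in = p_in, p_out = p_out,
                          seed = seed, heterogeneous = heterogeneous)
      ),
      class = "planted_fixture"
    )
  })
}

#' @export
print.planted_fixture <- function(x, ...) {
  cat("Planted-partition fixture:", igraph::vcount(x$graph), "nodes,",
      igraph::ecount(x$graph), "edges,",
      length(x$parameters$sizes), "blocks\n")
  invisible(x)
}

#' Synthetic pathway annotations concentrated in planted communities
#'
#' Emulates pathway gene sets whose members cluster inside network
#' communities: each pathway picks a home block from the ground-truth
#' partition, samples `round(purity * size)` genes from it and the
#' remainder uniformly from the other blocks. Broad categories are
#' assigned round-robin. The annotation universe is the full node set
#' of the truth partition.
#'
#' @param truth A [partition()] giving the planted blocks.
#' @param n_pathways Number of pathways (>= 0).
#' @param size_range Length-2 integer vector (min, max pathway size).
#' @param purity Fraction of each pathway drawn from its home block,
#'   in `[0, 1]`.
#' @param n_categories Number of broad category labels (default 6).
#' @param seed Integer seed.
#' @return An [annotation_set()].
#' @export
synthetic_annotation <- function(truth, n_pathways, size_range,
                                 purity = 1, n_categories = 6L,
                                 seed = 1L) {
  stopifnot(purity >= 0, purity <= 1, n_pathways >= 0)
  blocks <- partition_blocks(truth)
  universe <- names(truth$membership)
  if (n_pathways == 0L) {
    return(annotation_set(stats::setNames(list(), character(0)),
                          universe = universe))
  }
  max_home <- max(vapply(blocks, length, integer(1)))
  if (round(purity * size_range[2L]) > max_home ||
      size_range[2L] > length(universe)) {
    stop("pathway sizes infeasible for the given blocks")
  }
  cats <- paste0("cat", seq_len(n_categories))
  with_seed(seed, {
    pathways <- vector("list", n_pathways)
    for (pw in seq_len(n_pathways)) {
      size <- sample(seq(size_range[1L], size_range[2L]), 1L)
      feasible <- which(vapply(blocks, length, integer(1)) >=
                          round(purity * size))
      home <- feasible[sample.int(length(feasible), 1L)]
      n_home <- round(purity * size)
      inside <- sample(blocks[[home]], n_home)
      outside_pool <- setdiff(universe, blocks[[home]])
      outside <- if (size - n_home > 0) {
        sample(outside_pool, size - n_home)
      } else {
        character(0)
      }
      pathways[[pw]] <- c(inside, outside)
    }
    names(pathways) <- sprintf("pathway_%02d", seq_len(n_pathways))
    annotation_set(
      pathways,
      category = stats::setNames(rep_len(cats, n_pathways),
                                 names(pathways)),
      universe = universe
    )
  })
}

#' Synthetic ortholog pair table between two gene universes
#'
#' Builds a partial many-to-many mapping: `round(coverage * |A|)`
#' source genes each map to a distinct target gene, and a
#' `many_to_many_rate` fraction of the mapped sources receive a second
#' (distinct) target.
#'
#' @param genes_a,genes_b Character vectors of source and target genes.
#' @param coverage Fraction of source genes mapped, in `[0, 1]`.
#' @param many_to_many_rate Fraction of mapped sources with a second
#'   target, in `[0, 1]`.
#' @param seed Integer seed.
#' @return A data frame with columns `source`, `target`.
#' @export
synthetic_ortholog_table <- function(genes_a, genes_b, coverage = 0.5,
                                     many_to_many_rate = 0, seed = 1L) {
  stopifnot(coverage >= 0, coverage <= 1,
            many_to_many_rate >= 0, many_to_many_rate <= 1)
  genes_a <- unique(as.character(genes_a))
  genes_b <- unique(as.character(genes_b))
  n_map <- round(coverage * length(genes_a))
  n_second <- round(many_to_many_rate * n_map)
  if (n_map + n_second > length(genes_b)) {
    stop("not enough target genes for the requested coverage")
  }
  if (n_map == 0L) {
    return(data.frame(source = character(0), target = character(0)))
  }
  with_seed(seed, {
    src <- sample(genes_a, n_map)
    tgt <- sample(genes_b, n_map + n_second)
    df <- data.frame(source = src, target = tgt[seq_len(n_map)])
    if (n_second > 0L) {
      df <- rbind(df, data.frame(
        source = src[seq_len(n_second)],
        target = tgt[n_map + seq_len(n_second)]
      ))
    }
    df[order(df$source, df$target), , drop = FALSE]
  })
}
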