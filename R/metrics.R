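#' Compare two partitions with Rand index, adjusted Rand index and NMI
#'
#' All three measures are computed from the confusion matrix
#' \eqn{N_{ij}} cross-tabulating the two community assignments over the
#' shared node set:
#' * Rand index: \eqn{RI = (n_{00} + n_{11}) / \binom{N}{2}}, the
#'   probability that a random node pair is classified concordantly.
#' * Adjusted Rand index: the chance-corrected form built from
#'   \eqn{t_1 = \sum_i \binom{N_{i.}}{2}}, \eqn{t_2 = \sum_j
#'   \binom{N_{.j}}{2}} and \eqn{t_3 = 2 t_1 t_2 / (N(N-1))}.
#' * NMI: \eqn{2 I(A,B) / (H(A) + H(B))}, mutual information of the two
#'   label distributions normalized by their entropies (natural log;
#'   the base cancels).
#'
#' Degenerate cases: when either partition is a single block the NMI
#' denominator vanishes; NMI is defined as 1 when the partitions are
#' identical and 0 otherwise. ARI with zero denominator (both
#' partitions trivial and identical) is defined as 1.
#'
#' @param pa,pb Two [partition()]s over the same node set.
#' @return A list with elements `ri`, `ari`, `nmi`, the `pair_counts`
#'   (n11, n00, n01, n10) and the `confusion` matrix with margins.
#' @export
compare_partitions <- function(pa, pb) {
  stopifnot(inherits(pa, "node_partition"), inherits(pb, "node_partition"))
  nodes <- names(pa$membership)
  if (!setequal(nodes, names(pb$membership))) {
    stop("partitions are defined on different node sets")
  }
  la <- pa$membership[nodes]
  lb <- pb$membership[nodes]
  conf <- table(la, lb)
  N <- sum(conf)
  ni <- rowSums(conf)
  nj <- colSums(conf)

  choose2 <- function(x) x * (x - 1) / 2
  s_ij <- sum(choose2(conf))
  t1 <- sum(choose2(ni))
  t2 <- sum(choose2(nj))
  total_pairs <- choose2(N)

  n11 <- s_ij
  n01 <- t1 - s_ij # same in A, different in B
  n10 <- t2 - s_ij # same in B, different in A
  n00 <- total_pairs - t1 - t2 + s_ij

  ri <- if (total_pairs == 0) 1 else (n00 + n11) / total_pairs

  t3 <- if (N > 1) 2 * t1 * t2 / (N * (N - 1)) else 0
  ari_den <- (t1 + t2) / 2 - t3
  ari <- if (ari_den == 0) {
    # both partitions trivial: 1 when identical, else 0
    if (n01 == 0 && n10 == 0) 1 else 0
  } else {
    (s_ij - t3) / ari_den
  }

  nmi <- nmi_from_confusion(conf, identical_partitions = (n01 == 0 && n10 == 0))

  list(
    ri = ri, ari = ari, nmi = nmi,
    pair_counts = c(n11 = n11, n00 = n00, n01 = n01, n10 = n10),
    confusion = conf
  )
}

nmi_from_confusion <- function(conf, identical_partitions) {
  N <- sum(conf)
  ni <- rowSums(conf)
  nj <- colSums(conf)
  pos <- conf > 0
  num <- -2 * sum(conf[pos] * log(conf[pos] * N / outer(ni, nj)[pos]))
  den <- sum(ni * log(ni / N)) + sum(nj * log(nj / N))
  if (den == 0) {
    # one (or both) partitions trivial: entropy zero
    return(if (identical_partitions) 1 else 0)
  }
  num / den
}

#' Jaccard index of two node sets
#'
#' \eqn{J(A,B) = |A \cap B| / |A \cup B|}; \eqn{J(\emptyset,\emptyset)}
#' is defined as 0.
#'
#' @param set_a,set_b Character vectors (treated as sets).
#' @return A number in `[0, 1]`.
#' @export
jaccard_index <- function(set_a, set_b) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  u <- length(union(set_a, set_b))
  if (u == 0L) {
    return(0)
  }
  length(intersect(set_a, set_b)) / u
}

#' Jaccard matrix between the large communities of two partitions
#'
#' Rows are the communities of `pa` with at least `min_size` nodes,
#' sorted by decreasing size; columns likewise for `pb`. Entries are
#' the Jaccard index as a percentage (intersection over union of the
#' two node sets, times 100). Only communities with `min_size` or more
#' nodes are considered, mirroring the convention of restricting
#' community-level comparisons to blocks of 100+ genes.
#'
#' @param pa,pb Two [partition()]s (node sets may differ).
#' @param min_size Minimum community size to include (default 100).
#' @return A numeric matrix (possibly 0 x 0) with dimnames giving the
#'   community labels; values in `[0, 100]`.
#' @export
jaccard_matrix <- function(pa, pb, min_size = 100L) {
  ba <- keep_large_blocks(partition_blocks(pa), min_size)
  bb <- keep_large_blocks(partition_blocks(pb), min_size)
  jm <- matrix(0, nrow = length(ba), ncol = length(bb),
               dimnames = list(names(ba), names(bb)))
  for (i in seq_along(ba)) {
    for (j in seq_along(bb)) {
      jm[i, j] <- 100 * jaccard_index(ba[[i]], bb[[j]])
    }
  }
  jm
}

keep_large_blocks <- function(blocks, min_size) {
  blocks <- blocks[vapply(blocks, length, integer(1)) >= min_size]
  sizes <- vapply(blocks, length, integer(1))
  blocks[order(-sizes, names(blocks))]
}

#' Match communities across two partitions from a Jaccard matrix
#'
#' For each column (community of the second partition) the row with the
#' highest Jaccard value is selected; ties are broken in favour of the
#' larger row community (earlier row, since rows are sorted by
#' decreasing size). Columns whose best value is 0 are flagged as
#' having no overlap.
#'
#' @param jm A matrix from [jaccard_matrix()].
#' @return A data frame with columns `row`, `column`, `jaccard_pct`,
#'   `no_overlap`; zero rows for an empty matrix.
#' @export
match_communities <- function(jm) {
  if (length(jm) == 0L || ncol(jm) == 0L) {
    return(data.frame(row = character(0), column = character(0),
                      jaccard_pct = numeric(0), no_overlap = logical(0)))
  }
  best_row <- apply(jm, 2L, which.max) # first max = largest community
  data.frame(
    row = rownames(jm)[best_row],
    column = colnames(jm),
    jaccard_pct = jm[cbind(best_row, seq_len(ncol(jm)))],
    no_overlap = jm[cbind(best_row, seq_len(ncol(jm)))] == 0,
    row.names = NULL
  )
}

#' Overlap percentage between two gene sets of known sizes
#'
#' The reporting convention for "percent overlap" between two matched
#' communities or enriched gene sets: the common count divided by the
#' size of the larger set, times 100, rounded to the nearest integer
#' (half away from zero).
#'
#' @param size_a,size_b Sizes of the two sets (at least one positive).
#' @param common Size of their intersection.
#' @return An integer percentage.
#' @export
overlap_percent <- function(size_a, size_b, common) {
  if (max(size_a, size_b) <= 0) {
    stop("at least one set must be non-empty")
  }
  if (common < 0 || common > min(size_a, size_b)) {
    stop("common must lie between 0 and min(size_a, size_b)")
  }
  x <- 100 * common / max(size_a, size_b)
  # round half away from zero (x is non-negative here)
  as.integer(floor(x + 0.5))
}
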