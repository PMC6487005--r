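#' Pathway annotation set
#'
#' Bundles a pathway -> gene-set mapping, an optional pathway -> broad
#' category mapping and the background gene universe used as the
#' enrichment null. Every annotated gene must belong to the universe;
#' pathway sets must be non-empty.
#'
#' @param pathways Named list of character vectors (pathway id -> gene
#'   set).
#' @param category Optional named character vector (pathway id ->
#'   category label).
#' @param universe Background gene universe; defaults to the union of
#'   all pathway genes.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(pathways, category = NULL, universe = NULL) {
  pathways <- lapply(pathways, function(x) unique(as.character(x)))
  if (length(pathways) > 0 &&
      any(vapply(pathways, length, integer(1)) == 0L)) {
    stop("pathway gene sets must be non-empty")
  }
  if (is.null(universe)) {
    universe <- unique(unlist(pathways, use.names = FALSE))
  }
  universe <- unique(as.character(universe))
  stray <- setdiff(unique(unlist(pathways, use.names = FALSE)), universe)
  if (length(stray) > 0L) {
    stop("annotated gene(s) outside the universe: ",
         paste(utils::head(stray, 5L), collapse = ", "))
  }
  if (!is.null(category)) {
    category <- stats::setNames(as.character(category), names(category))
  }
  structure(list(pathways = pathways, category = category,
                 universe = universe),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("Annotation set:", length(x$pathways), "pathways,",
      length(x$universe), "genes in the universe\n")
  invisible(x)
}

#' Read pathway gene sets from a GMT file
#'
#' @param gmt_path Path to a GMT file
#'   (`pathway<TAB>description<TAB>gene...`).
#' @param category_path Optional two-column TSV
#'   (`pathway<TAB>category`).
#' @param universe Optional background universe (default: union of GMT
#'   genes).
#' @return An [annotation_set()].
#' @export
read_annotation_gmt <- function(gmt_path, category_path = NULL,
                                universe = NULL) {
  pathways <- fgsea::gmtPathways(gmt_path)
  category <- NULL
  if (!is.null(category_path)) {
    df <- utils::read.table(category_path, sep = "\t", header = FALSE,
                            colClasses = "character", quote = "")
    category <- stats::setNames(df[[2L]], df[[1L]])
  }
  annotation_set(pathways, category = category, universe = universe)
}

#' Write an annotation set to GMT (+ optional category TSV)
#'
#' @param ann An [annotation_set()].
#' @param gmt_path Output GMT path.
#' @param category_path Optional output path for the category TSV.
#' @return `gmt_path`, invisibly.
#' @export
write_annotation_gmt <- function(ann, gmt_path, category_path = NULL) {
  lines <- vapply(names(ann$pathways), function(pw) {
    paste(c(pw, pw, ann$pathways[[pw]]), collapse = "\t")
  }, character(1))
  writeLines(lines, gmt_path)
  if (!is.null(category_path) && !is.null(ann$category)) {
    utils::write.table(
      data.frame(pathway = names(ann$category), category = ann$category),
      category_path, sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE
    )
  }
  invisible(gmt_path)
}

#' Hypergeometric pathway enrichment of a gene set
#'
#' For a query gene set (typically a community) and each pathway,
#' computes the overlap `s`, the one-sided hypergeometric tail
#' probability \eqn{P(X \ge s)} of drawing `k` genes from a universe of
#' `N` containing `b` pathway genes (Fisher's exact one-sided test),
#' and the fold enrichment \eqn{FE = (s/b) / (k/N)}. Only the part of
#' the query inside the universe counts towards `k`, mirroring
#' annotation services that cannot annotate every input gene.
#' Benjamini-Hochberg q-values are reported alongside the raw
#' p-values, but filtering uses the raw p-value. Rows are kept when
#' `s > min_count` and `p <= p_cutoff` and returned sorted by
#' increasing p.
#'
#' @param query Character vector of query genes.
#' @param ann An [annotation_set()].
#' @param min_count Keep pathways with strictly more than this many
#'   query genes (default 10).
#' @param p_cutoff Keep pathways with `p <= p_cutoff` (default 0.01).
#' @return A data frame with columns `pathway`, `category`, `count`
#'   (s), `b`, `k`, `N`, `p_value`, `q_value`, `fold_enrichment` and a
#'   list column `genes` holding the overlapping genes.
#' @export
enrich_gene_set <- function(query, ann, min_count = 10L,
                            p_cutoff = 0.01) {
  stopifnot(inherits(ann, "annotation_set"))
  if (length(ann$universe) == 0L) {
    stop("annotation universe is empty")
  }
  query <- intersect(unique(as.character(query)), ann$universe)
  k <- length(query)
  if (k == 0L) {
    stop("query set shares no genes with the annotation universe")
  }
  N <- length(ann$universe)
  rows <- lapply(names(ann$pathways), function(pw) {
    genes <- intersect(ann$pathways[[pw]], query)
    s <- length(genes)
    b <- length(ann$pathways[[pw]])
    p <- stats::phyper(s - 1, b, N - b, k, lower.tail = FALSE)
    data.frame(
      pathway = pw,
      category = if (is.null(ann$category)) NA_character_ else
        unname(ann$category[pw]),
      count = s, b = b, k = k, N = N,
      p_value = p,
      fold_enrichment = (s / b) / (k / N),
      genes = I(list(genes)),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    res <- data.frame(pathway = character(0), category = character(0),
                      count = integer(0), b = integer(0), k = integer(0),
                      N = integer(0), p_value = numeric(0),
                      fold_enrichment = numeric(0),
                      genes = I(list()))
  }
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res <- res[res$count > min_count & res$p_value <= p_cutoff, ,
             drop = FALSE]
  res <- res[order(res$p_value, res$pathway), , drop = FALSE]
  rownames(res) <- NULL
  res[, c("pathway", "category", "count", "b", "k", "N", "p_value",
          "q_value", "fold_enrichment", "genes")]
}

#' Compare the enrichment profiles of two communities
#'
#' For every pathway retained in either enrichment result, tabulates
#' the per-side enriched gene counts and the number of genes common to
#' both; overall, the unique genes across all retained pathways are
#' pooled per side and summarized with [overlap_percent()]. A pathway
#' enriched on one side only gets a zero count on the other (the
#' "blank column" behavior of side-by-side pathway tables).
#'
#' @param rows_a,rows_b Results of [enrich_gene_set()] computed against
#'   the same annotation universe.
#' @return A list with `per_pathway` (data frame: `pathway`,
#'   `category`, `count_a`, `count_b`, `common`) and `overall` (list:
#'   `unique_a`, `unique_b`, `common`, `overlap_percent`).
#' @export
compare_enriched <- function(rows_a, rows_b) {
  if (nrow(rows_a) > 0 && nrow(rows_b) > 0 &&
      rows_a$N[1L] != rows_b$N[1L]) {
    stop("enrichment results use different annotation universes")
  }
  pws <- union(rows_a$pathway, rows_b$pathway)
  ga <- stats::setNames(rows_a$genes, rows_a$pathway)
  gb <- stats::setNames(rows_b$genes, rows_b$pathway)
  cat_of <- c(stats::setNames(rows_a$category, rows_a$pathway),
              stats::setNames(rows_b$category, rows_b$pathway))
  per <- do.call(rbind, lapply(pws, function(pw) {
    a <- if (pw %in% names(ga)) ga[[pw]] else character(0)
    b <- if (pw %in% names(gb)) gb[[pw]] else character(0)
    data.frame(pathway = pw, category = unname(cat_of[pw]),
               count_a = length(a), count_b = length(b),
               common = length(intersect(a, b)),
               stringsAsFactors = FALSE)
  }))
  if (is.null(per)) {
    per <- data.frame(pathway = character(0), category = character(0),
                      count_a = integer(0), count_b = integer(0),
                      common = integer(0))
  }
  ua <- unique(unlist(rows_a$genes, use.names = FALSE))
  ub <- unique(unlist(rows_b$genes, use.names = FALSE))
  common <- length(intersect(ua, ub))
  ov <- if (length(ua) == 0L && length(ub) == 0L) NA_integer_ else
    overlap_percent(length(ua), length(ub), common)
  list(
    per_pathway = per[order(per$pathway), , drop = FALSE],
    overall = list(unique_a = length(ua), unique_b = length(ub),
                   common = common, overlap_percent = ov)
  )
}

#' Broad-category composition of an enrichment profile
#'
#' Pools the enriched genes of the retained pathways by broad category
#' and expresses each category's unique gene count as a percentage of
#' the unique genes across all retained pathways (the pie-chart
#' summary). Genes annotated to pathways of several categories count
#' towards each, so percentages may sum to more than 100.
#'
#' @param rows A result of [enrich_gene_set()]; every row needs a
#'   category.
#' @return Named numeric vector of percentages, one per category.
#' @export
category_composition <- function(rows) {
  if (nrow(rows) == 0L) {
    return(stats::setNames(numeric(0), character(0)))
  }
  if (anyNA(rows$category)) {
    stop("every enriched pathway needs a category label")
  }
  total <- length(unique(unlist(rows$genes, use.names = FALSE)))
  by_cat <- split(rows$genes, rows$category)
  vapply(by_cat, function(gl) {
    100 * length(unique(unlist(gl, use.names = FALSE))) / total
  }, numeric(1))
}

#' Distribution of each pathway's enriched genes across communities
#'
#' For every community of a partition, the overlap count of each
#' pathway is tabulated together with whether the community-level
#' hypergeometric p-value passes the cutoff; pathways significantly
#' enriched (with `count > min_count`) in at least one community are
#' reported with a per-pathway total and the pathway size b. On
#' annotations concentrated inside communities, most of a pathway's
#' genes fall into a single significant column.
#'
#' @param p A [partition()].
#' @param ann An [annotation_set()].
#' @param min_count,p_cutoff Filters as in [enrich_gene_set()].
#' @return A list with `counts` (pathway x community matrix of overlap
#'   counts), `significant` (logical matrix, p <= cutoff and count >
#'   min_count), `total` (row sums) and `b` (pathway sizes).
#' @export
pathway_community_distribution <- function(p, ann, min_count = 10L,
                                           p_cutoff = 0.01) {
  stopifnot(inherits(p, "node_partition"), inherits(ann, "annotation_set"))
  blocks <- partition_blocks(p)
  blocks <- blocks[order(-vapply(blocks, length, integer(1)),
                         names(blocks))]
  N <- length(ann$universe)
  pws <- names(ann$pathways)
  counts <- matrix(0L, nrow = length(pws), ncol = length(blocks),
                   dimnames = list(pws, names(blocks)))
  signif <- counts == 1L # all FALSE
  for (ci in seq_along(blocks)) {
    query <- intersect(blocks[[ci]], ann$universe)
    kk <- length(query)
    if (kk == 0L) next
    for (pi in seq_along(pws)) {
      set <- ann$pathways[[pi]]
      s <- length(intersect(set, query))
      counts[pi, ci] <- s
      pval <- stats::phyper(s - 1, length(set), N - length(set), kk,
                            lower.tail = FALSE)
      signif[pi, ci] <- (pval <= p_cutoff) && (s > min_count)
    }
  }
  keep <- rowSums(signif) > 0L
  list(
    counts = counts[keep, , drop = FALSE],
    significant = signif[keep, , drop = FALSE],
    total = rowSums(counts[keep, , drop = FALSE]),
    b = vapply(ann$pathways, length, integer(1))[keep]
  )
}

#' Map a gene set through an ortholog pair table
#'
#' Returns the image of the query under the (possibly many-to-many)
#' source -> target relation, plus the number of query genes with no
#' ortholog.
#'
#' @param genes Character vector of source genes.
#' @param table Data frame whose first two columns are (source, target)
#'   pairs.
#' @return A list with `mapped` (character vector of target genes) and
#'   `unmapped` (count of query genes without a pair).
#' @export
map_orthologs <- function(genes, table) {
  genes <- unique(as.character(genes))
  if (nrow(table) == 0L) {
    return(list(mapped = character(0), unmapped = length(genes)))
  }
  src <- as.character(table[[1L]])
  tgt <- as.character(table[[2L]])
  hit <- src %in% genes
  list(
    mapped = unique(tgt[hit]),
    unmapped = sum(!(genes %in% src))
  )
}
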