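#' Run the full community-comparison pipeline
#'
#' Orchestrates the analysis flow end to end: detect communities with
#' every configured method (stochastic methods via [best_of_runs()],
#' deterministic ones once), compare all method pairs with RI/ARI/NMI,
#' rank pairs by similarity, build Jaccard matrices and matched
#' community pairs for the most similar and most dissimilar method
#' pair, and - when annotations are supplied - compare the enrichment
#' profiles of matched communities, summarize broad-category
#' compositions, and tabulate how each pathway's genes distribute over
#' each method's communities. Optionally runs the node-deletion
#' robustness analysis per method. Deterministic given the
#' configuration and master seed.
#'
#' @param config A list with elements:
#'   \describe{
#'     \item{graph}{an igraph graph (or `edges`, a path for
#'       [read_edge_list()]).}
#'     \item{methods}{character vector of method names understood by
#'       [detector()].}
#'     \item{seed}{master seed (default 1).}
#'     \item{runs}{runs per stochastic method (default 10); seeds are
#'       drawn without replacement from `[0, 10000]`.}
#'     \item{min_size}{community size floor for Jaccard matrices
#'       (default 100).}
#'     \item{annotations}{optional [annotation_set()].}
#'     \item{min_count, p_cutoff}{enrichment filters (defaults 10,
#'       0.01).}
#'     \item{min_communities}{sanity filter: methods splitting the
#'       network into fewer communities than this are excluded from
#'       the dissimilar-pair selection (default 2).}
#'     \item{robustness}{optional list(repeats, fraction) enabling the
#'       robustness stage.}
#'     \item{method_args}{optional named list of per-method tuning
#'       arguments forwarded to [detector()].}
#'   }
#' @return A list of class `comparison_report`; see Details.
#' @details The report holds `summary` (per-method Q, community count
#'   and per-community node/edge sizes), `runs` (all stochastic runs),
#'   `metrics` (RI/ARI/NMI matrices), `pair_ranking` (method pairs
#'   sorted by mean metric rank), `similar_pair` / `dissimilar_pair`
#'   each with the Jaccard matrix and matched columns, `enrichment`
#'   (per matched community pair of the similar and dissimilar method
#'   pair), `category_composition`, `pathway_distribution` and
#'   `robustness` (when configured).
#' @export
run_comparison <- function(config) {
  cfg <- config
  if (is.null(cfg$graph)) {
    if (is.null(cfg$edges)) {
      stop("config needs a graph or an edges file path")
    }
    cfg$graph <- read_edge_list(cfg$edges)
  }
  if (is.null(cfg$methods) || length(cfg$methods) == 0L) {
    stop("config needs at least one method")
  }
  known <- c("girvan_newman", "fast_greedy", "louvain", "leading_eigen",
             "spinglass", "combo", "conclude")
  bad <- setdiff(cfg$methods, known)
  if (length(bad) > 0L) {
    stop("unknown method name(s): ", paste(bad, collapse = ", "))
  }
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  runs <- if (is.null(cfg$runs)) 10L else as.integer(cfg$runs)
  min_size <- if (is.null(cfg$min_size)) 100L else as.integer(cfg$min_size)
  min_count <- if (is.null(cfg$min_count)) 10L else cfg$min_count
  p_cutoff <- if (is.null(cfg$p_cutoff)) 0.01 else cfg$p_cutoff
  min_comms <- if (is.null(cfg$min_communities)) 2L else cfg$min_communities
  g <- cfg$graph

  # --- detection -----------------------------------------------------
  partitions <- list()
  run_tables <- list()
  summary_rows <- list()
  for (mi in seq_along(cfg$methods)) {
    mname <- cfg$methods[mi]
    margs <- if (!is.null(cfg$method_args[[mname]]))
      cfg$method_args[[mname]] else list()
    det <- do.call(detector, c(list(mname), margs))
    if (isTRUE(attr(det, "stochastic"))) {
      res <- best_of_runs(det, g, n_runs = runs,
                          seed = derive_seed(seed, mi))
      partitions[[mname]] <- rank_by_size(res$best$partition)
      run_tables[[mname]] <- res$runs
      q <- res$best$q
      rt <- res$best$runtime_s
    } else {
      t0 <- proc.time()[["elapsed"]]
      p <- det(g, seed)
      rt <- proc.time()[["elapsed"]] - t0
      partitions[[mname]] <- rank_by_size(p)
      gq <- if (setequal(names(p$membership), igraph::V(g)$name)) g else
        igraph::induced_subgraph(g, names(p$membership))
      q <- modularity_q(gq, p)
    }
    summary_rows[[mname]] <- data.frame(
      method = mname, q = q,
      n_communities = n_communities(partitions[[mname]]),
      runtime_s = rt
    )
  }
  summary <- do.call(rbind, summary_rows)
  rownames(summary) <- NULL
  community_sizes <- lapply(partitions, function(p)
    community_size_table(g, p, min_size))

  # --- topological comparison ---------------------------------------
  methods <- names(partitions)
  nm <- length(methods)
  metr <- list(ri = diag(1, nm), ari = diag(1, nm), nmi = diag(1, nm))
  for (mt in names(metr)) {
    dimnames(metr[[mt]]) <- list(methods, methods)
  }
  pair_rows <- list()
  if (nm >= 2L) {
    for (i in seq_len(nm - 1L)) {
      for (j in seq((i + 1L), nm)) {
        shared <- intersect(names(partitions[[i]]$membership),
                            names(partitions[[j]]$membership))
        cmp <- compare_partitions(
          partition(partitions[[i]]$membership[shared]),
          partition(partitions[[j]]$membership[shared])
        )
        for (mt in names(metr)) {
          metr[[mt]][i, j] <- metr[[mt]][j, i] <- cmp[[mt]]
        }
        pair_rows[[length(pair_rows) + 1L]] <- data.frame(
          method_a = methods[i], method_b = methods[j],
          ri = cmp$ri, ari = cmp$ari, nmi = cmp$nmi
        )
      }
    }
  }
  pair_ranking <- NULL
  similar <- dissimilar <- NULL
  if (length(pair_rows) > 0L) {
    pair_ranking <- do.call(rbind, pair_rows)
    pair_ranking$mean_rank <- rowMeans(cbind(
      rank(-pair_ranking$ri), rank(-pair_ranking$ari),
      rank(-pair_ranking$nmi)))
    # do RI, ARI and NMI rank the pairs identically? when not, the full
    # ranking table is the deliverable rather than a single "best pair"
    pair_ranking$rankings_agree <-
      all(rank(-pair_ranking$ri) == rank(-pair_ranking$ari)) &&
      all(rank(-pair_ranking$ari) == rank(-pair_ranking$nmi))
    pair_ranking <- pair_ranking[order(pair_ranking$mean_rank), ,
                                 drop = FALSE]
    rownames(pair_ranking) <- NULL
    similar <- pair_detail(partitions, pair_ranking[1L, ], min_size)
    # dissimilar pair: both methods must pass the fragmentation sanity
    # filter (at least min_communities communities of >= min_size nodes)
    ok <- vapply(methods, function(mm) {
      sum(table(partitions[[mm]]$membership) >= min_size) >= 1L &&
        n_communities(partitions[[mm]]) >= min_comms
    }, logical(1))
    cand <- pair_ranking[pair_ranking$method_a %in% methods[ok] &
                           pair_ranking$method_b %in% methods[ok], ,
                         drop = FALSE]
    if (nrow(cand) > 0L) {
      dissimilar <- pair_detail(partitions, cand[nrow(cand), ], min_size)
    }
  }

  # --- functional comparison ----------------------------------------
  enrichment <- NULL
  categories <- NULL
  pathway_dist <- NULL
  if (!is.null(cfg$annotations)) {
    ann <- cfg$annotations
    enrichment <- list()
    if (!is.null(similar)) {
      enrichment$similar <- matched_pair_enrichment(
        partitions, similar, ann, min_count, p_cutoff)
    }
    if (!is.null(dissimilar)) {
      enrichment$dissimilar <- matched_pair_enrichment(
        partitions, dissimilar, ann, min_count, p_cutoff)
    }
    if (!is.null(ann$category)) {
      categories <- lapply(partitions, function(p) {
        blocks <- keep_large_blocks(partition_blocks(p), min_size)
        lapply(blocks, function(bl) {
          rows <- try(enrich_gene_set(bl, ann, min_count, p_cutoff),
                      silent = TRUE)
          if (inherits(rows, "try-error") || nrow(rows) == 0L)
            return(stats::setNames(numeric(0), character(0)))
          category_composition(rows)
        })
      })
    }
    pathway_dist <- lapply(partitions, function(p)
      pathway_community_distribution(p, ann, min_count, p_cutoff))
  }

  # --- robustness -----------------------------------------------------
  robustness <- NULL
  if (!is.null(cfg$robustness)) {
    robustness <- list()
    for (mi in seq_along(methods)) {
      mname <- methods[mi]
      margs <- if (!is.null(cfg$method_args[[mname]]))
        cfg$method_args[[mname]] else list()
      det <- do.call(detector, c(list(mname), margs))
      robustness[[mname]] <- robustness_run(
        g, det,
        repeats = cfg$robustness$repeats,
        fraction = cfg$robustness$fraction,
        min_size = min_size,
        seed = derive_seed(seed, 1000L + mi)
      )
    }
  }

  structure(
    list(
      summary = summary, community_sizes = community_sizes,
      runs = run_tables, partitions = partitions,
      metrics = metr, pair_ranking = pair_ranking,
      similar_pair = similar, dissimilar_pair = dissimilar,
      enrichment = enrichment, category_composition = categories,
      pathway_distribution = pathway_dist, robustness = robustness,
      config = list(seed = seed, runs = runs, min_size = min_size,
                    methods = cfg$methods)
    ),
    class = "comparison_report"
  )
}

# Per-community node and edge counts (largest first, >= min_size).
community_size_table <- function(g, p, min_size) {
  blocks <- keep_large_blocks(partition_blocks(p), 1L)
  rows <- lapply(names(blocks), function(lb) {
    sub <- igraph::induced_subgraph(g, intersect(blocks[[lb]],
                                                 igraph::V(g)$name))
    data.frame(community = lb, n_nodes = length(blocks[[lb]]),
               n_edges = igraph::ecount(sub))
  })
  tbl <- do.call(rbind, rows)
  tbl[tbl$n_nodes >= min_size | seq_len(nrow(tbl)) <= 2L, , drop = FALSE]
}

pair_detail <- function(partitions, row, min_size) {
  pa <- partitions[[row$method_a]]
  pb <- partitions[[row$method_b]]
  jm <- jaccard_matrix(pa, pb, min_size)
  list(method_a = row$method_a, method_b = row$method_b,
       ri = row$ri, ari = row$ari, nmi = row$nmi,
       jaccard = jm, matched = match_communities(jm))
}

matched_pair_enrichment <- function(partitions, pair, ann, min_count,
                                    p_cutoff) {
  pa <- partition_blocks(partitions[[pair$method_a]])
  pb <- partition_blocks(partitions[[pair$method_b]])
  out <- list()
  for (r in seq_len(nrow(pair$matched))) {
    row_lab <- pair$matched$row[r]
    col_lab <- pair$matched$column[r]
    ra <- try(enrich_gene_set(pa[[row_lab]], ann, min_count, p_cutoff),
              silent = TRUE)
    rb <- try(enrich_gene_set(pb[[col_lab]], ann, min_count, p_cutoff),
              silent = TRUE)
    if (inherits(ra, "try-error") || inherits(rb, "try-error")) next
    out[[paste0(pair$method_a, ":", row_lab, "_vs_",
                pair$method_b, ":", col_lab)]] <-
      compare_enriched(ra, rb)
  }
  out
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Community-comparison report\n")
  print(x$summary)
  if (!is.null(x$pair_ranking) && nrow(x$pair_ranking) > 0L) {
    top <- x$pair_ranking[1L, ]
    cat("most similar pair:", top$method_a, "vs", top$method_b,
        sprintf("(RI %.3f, ARI %.3f, NMI %.3f)\n",
                top$ri, top$ari, top$nmi))
  }
  invisible(x)
}

#' Write the tabular artifacts of a comparison report to a directory
#'
#' Emits TSV tables (method summary, run tables, metric matrices,
#' Jaccard matrices, matched pairs, per-pathway comparisons, pathway
#' distributions) and JSON summaries (overall overlaps, category
#' compositions, robustness). Partitions are written as two-column
#' TSVs.
#'
#' @param report A `comparison_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, name, rn = FALSE) {
    utils::write.table(x, file.path(dir, name), sep = "\t",
                       quote = FALSE, row.names = rn,
                       col.names = !is.null(colnames(x)))
  }
  tsv(report$summary, "method_summary.tsv")
  for (mname in names(report$runs)) {
    tsv(report$runs[[mname]], paste0("runs_", mname, ".tsv"))
  }
  for (mt in names(report$metrics)) {
    tsv(report$metrics[[mt]], paste0("metric_", mt, ".tsv"), rn = TRUE)
  }
  if (!is.null(report$pair_ranking)) {
    tsv(report$pair_ranking, "pair_ranking.tsv")
  }
  for (side in c("similar_pair", "dissimilar_pair")) {
    pr <- report[[side]]
    if (is.null(pr)) next
    tsv(round(pr$jaccard, 2), paste0(side, "_jaccard.tsv"), rn = TRUE)
    tsv(pr$matched, paste0(side, "_matched.tsv"))
  }
  for (mname in names(report$partitions)) {
    write_partition(report$partitions[[mname]],
                    file.path(dir, paste0("partition_", mname, ".tsv")))
  }
  summaries <- list()
  if (!is.null(report$enrichment)) {
    for (side in names(report$enrichment)) {
      for (pairname in names(report$enrichment[[side]])) {
        cmpE <- report$enrichment[[side]][[pairname]]
        safe <- gsub("[^A-Za-z0-9_.-]", "_", pairname)
        tsv(cmpE$per_pathway,
            paste0("enrichment_", side, "_", safe, ".tsv"))
        summaries$enrichment_overlap[[side]][[pairname]] <- cmpE$overall
      }
    }
  }
  if (!is.null(report$category_composition)) {
    summaries$category_composition <- report$category_composition
  }
  if (!is.null(report$pathway_distribution)) {
    for (mname in names(report$pathway_distribution)) {
      pd <- report$pathway_distribution[[mname]]
      if (nrow(pd$counts) == 0L) next
      out <- data.frame(pathway = rownames(pd$counts), pd$counts,
                        total = pd$total, b = pd$b,
                        check.names = FALSE)
      tsv(out, paste0("pathway_distribution_", mname, ".tsv"))
    }
  }
  if (!is.null(report$robustness)) {
    for (mname in names(report$robustness)) {
      rb <- report$robustness[[mname]]
      tsv(data.frame(repeat_index = seq_along(rb$avg_max),
                     avg_max = rb$avg_max),
          paste0("robustness_", mname, ".tsv"))
      summaries$robustness[[mname]] <-
        list(mean = rb$mean, sd = rb$sd,
              fraction = rb$parameters$fraction,
              repeats = rb$parameters$repeats)
    }
  }
  jsonlite::write_json(summaries, file.path(dir, "summaries.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
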