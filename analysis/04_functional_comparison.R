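#!/usr/bin/env Rscript
# Stage 4: functional comparison via pathway enrichment.
#
# Hypergeometric enrichment of every large community against the
# synthetic pathway annotation, side-by-side comparison of the matched
# community pairs from stage 3, broad-category composition of the top
# community, the pathway x community gene-distribution table, and the
# ortholog-mapped cross-network comparison.

suppressPackageStartupMessages(library(bionetcomm))

out <- "results/function"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
min_size <- 50L
min_count <- 10L
p_cutoff <- 0.01

ann <- read_annotation_gmt("results/data/primary_pathways.gmt",
                           "results/data/primary_categories.tsv")
parts <- local({
  files <- list.files("results/detection", "^partition_",
                      full.names = TRUE)
  ps <- lapply(files, read_partition)
  names(ps) <- sub("^partition_(.*)\\.tsv$", "\\1", basename(files))
  ps
})

# matched-pair enrichment comparison for the most similar method pair
matched <- utils::read.table("results/topology/matched_similar.tsv",
                             header = TRUE, sep = "\t",
                             colClasses = c("character", "character",
                                            "numeric", "logical"))
ranking <- utils::read.table("results/topology/pair_ranking.tsv",
                             header = TRUE, sep = "\t")
method_a <- ranking$method_a[1]
method_b <- ranking$method_b[1]
blocks_a <- partition_blocks(parts[[method_a]])
blocks_b <- partition_blocks(parts[[method_b]])
for (r in seq_len(nrow(matched))) {
  ra <- enrich_gene_set(blocks_a[[matched$row[r]]], ann, min_count,
                        p_cutoff)
  rb <- enrich_gene_set(blocks_b[[matched$column[r]]], ann, min_count,
                        p_cutoff)
  cmp <- compare_enriched(ra, rb)
  stem <- sprintf("pair_%s%s_vs_%s%s", method_a, matched$row[r],
                  method_b, matched$column[r])
  utils::write.table(cmp$per_pathway, file.path(out, paste0(stem, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf(
    "%s community %s vs %s community %s: %d vs %d enriched genes, %d common (%s%% overlap)\n",
    method_a, matched$row[r], method_b, matched$column[r],
    cmp$overall$unique_a, cmp$overall$unique_b, cmp$overall$common,
    cmp$overall$overlap_percent))
}

# broad-category composition of each method's largest community
comp <- lapply(names(parts), function(mn) {
  big <- partition_blocks(parts[[mn]])[[
    names(sort(table(parts[[mn]]$membership), decreasing = TRUE))[1]]]
  rows <- enrich_gene_set(big, ann, min_count, p_cutoff)
  if (nrow(rows) == 0) return(NULL)
  as.list(round(category_composition(rows), 1))
})
names(comp) <- names(parts)
jsonlite::write_json(comp[!vapply(comp, is.null, logical(1))],
                     file.path(out, "category_composition.json"),
                     auto_unbox = TRUE, pretty = TRUE)

# pathway gene distribution across communities, per method
for (mn in names(parts)) {
  pd <- pathway_community_distribution(parts[[mn]], ann, min_count,
                                       p_cutoff)
  if (nrow(pd$counts) == 0) next
  tab <- data.frame(pathway = rownames(pd$counts), pd$counts,
                    total = pd$total, b = pd$b, check.names = FALSE)
  utils::write.table(tab,
                     file.path(out, paste0("pathway_distribution_", mn, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  loc <- mean(rowSums(pd$significant) == 1)
  cat(sprintf("%s: %.0f%% of enriched pathways significant in exactly one community\n",
              mn, 100 * loc))
}

# ortholog-mapped comparison: partner-network communities carried into
# the primary gene universe, then matched by Jaccard
partner <- read_edge_list("results/data/partner_edges.tsv")
orth <- utils::read.table("results/data/orthologs.tsv", sep = "\t",
                          colClasses = "character")
p_partner <- rank_by_size(louvain(partner, seed = 20260923L))
mapped_blocks <- lapply(partition_blocks(p_partner), function(bl)
  map_orthologs(bl, orth)$mapped)
mapped_blocks <- mapped_blocks[lengths(mapped_blocks) > 0]
# many-to-many images can collide; keep first occurrence per gene
keep <- !duplicated(unlist(mapped_blocks))
mapped_part <- partition(stats::setNames(
  rep(names(mapped_blocks), lengths(mapped_blocks))[keep],
  unlist(mapped_blocks)[keep]))
jm <- jaccard_matrix(mapped_part, parts[["louvain"]], min_size = 30)
utils::write.table(round(jm, 1), file.path(out, "jaccard_ortholog.tsv"),
                   sep = "\t", quote = FALSE, row.names = TRUE)
cat(sprintf("ortholog comparison: best cross-network Jaccard %.0f%%\n",
            max(jm)))
cat("wrote functional artifacts under", out, "\n")
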