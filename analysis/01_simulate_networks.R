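#!/usr/bin/env Rscript
# Stage 1: generate the study inputs.
#
# Two planted-partition interaction networks stand in for downloaded
# PPI snapshots: a primary network of four 100-node modules with
# heterogeneous (lognormal) degree propensities, and a smaller partner
# network of three 80-node modules for the cross-species comparison.
# Pathway annotations are concentrated inside the planted modules
# (purity 0.9) and a partial many-to-many ortholog table links the two
# gene universes. Everything is written as plain TSV/GMT so the later
# stages run from files alone.

suppressPackageStartupMessages(library(bionetcomm))

seed <- 20260923L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

primary <- planted_partition_graph(rep(100, 4), p_in = 0.3,
                                   p_out = 0.005, seed = seed,
                                   heterogeneous = TRUE)
write_edge_list(primary$graph, file.path(out, "primary_edges.tsv"))
write_partition(primary$truth, file.path(out, "primary_truth.tsv"))

ann <- synthetic_annotation(primary$truth, n_pathways = 24,
                            size_range = c(25, 60), purity = 0.9,
                            n_categories = 6, seed = seed + 1)
write_annotation_gmt(ann, file.path(out, "primary_pathways.gmt"),
                     file.path(out, "primary_categories.tsv"))

partner <- planted_partition_graph(rep(80, 3), p_in = 0.3,
                                   p_out = 0.005, seed = seed + 2,
                                   heterogeneous = TRUE)
# distinct identifier space for the partner species
partner_names <- paste0("h", igraph::V(partner$graph)$name)
partner_graph <- partner$graph
igraph::V(partner_graph)$name <- partner_names
partner_truth <- partition(stats::setNames(
  partner$truth$membership, partner_names))
write_edge_list(partner_graph, file.path(out, "partner_edges.tsv"))
write_partition(partner_truth, file.path(out, "partner_truth.tsv"))

orth <- synthetic_ortholog_table(partner_names,
                                 names(primary$truth$membership),
                                 coverage = 0.6,
                                 many_to_many_rate = 0.1,
                                 seed = seed + 3)
utils::write.table(orth, file.path(out, "orthologs.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE, col.names = FALSE)

deg <- degree_sequence(primary$graph)
cat(sprintf(
  "primary network: %d nodes, %d edges, degree range %d-%d (skewed: var/mean = %.1f)\n",
  igraph::vcount(primary$graph), igraph::ecount(primary$graph),
  min(deg$degree), max(deg$degree),
  stats::var(deg$degree) / mean(deg$degree)))
cat(sprintf("partner network: %d nodes, %d edges; ortholog pairs: %d\n",
            igraph::vcount(partner_graph), igraph::ecount(partner_graph),
            nrow(orth)))
cat("wrote inputs under", out, "\n")
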