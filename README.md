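# bionetcomm

Community detection in biological interaction networks is almost always
modularity maximization in disguise, and the many algorithms that do it
disagree in practice — on community sizes, on boundaries, and on the
biology the communities end up representing. `bionetcomm` is an R
toolkit for running that comparison end to end on protein-protein
interaction (PPI) style networks: detect communities with six
algorithms, quantify how similar the resulting partitions are, match
communities across methods, compare the matched communities'
pathway-enrichment profiles, and measure how stable each method's
communities are under random node deletion. Seeded generators for
planted-partition networks, concentrated pathway annotations and
partial ortholog tables make every stage runnable and testable with no
database access.

It is aimed at computational/systems biologists who need to pick (or
defend) a community detection method for a network analysis, and at
anyone who wants from-scratch, test-covered reference implementations
of the classic modularity family.

## The objective and the methods

All methods target the modularity of a partition $\{c_i\}$ of a graph
with adjacency $A_{ij}$, degrees $k_i$ and total edge weight $m$:

$$Q = \frac{1}{2m}\sum_{i,j}\Big[A_{ij} - \frac{k_i k_j}{2m}\Big]\,
\delta(c_i, c_j)$$

| function | strategy |
|---|---|
| `girvan_newman()` | divisive edge-betweenness removal, best dendrogram cut |
| `fast_greedy()` | agglomerative merging with sparse exact $\Delta Q$ bookkeeping |
| `louvain()` | two-phase local moves + aggregation, seeded sweep order |
| `leading_eigen()` | recursive spectral bisection of the modularity matrix |
| `spinglass()` | simulated annealing of the Potts Hamiltonian ($Q = -\mathcal{H}/2m - \sum_i k_i^2/(2m)^2$ at $\gamma = 1$) |
| `combo()` | best merge/split/shift via Kernighan–Lin series |
| `conclude()` | $\kappa$-path edge-centrality reweighting, then Louvain |

Partitions are compared with the Rand index, adjusted Rand index and
normalized mutual information (`compare_partitions()`); communities are
matched across methods with percentage Jaccard matrices
(`jaccard_matrix()`, `match_communities()`); matched communities are
compared functionally with one-sided hypergeometric enrichment and fold
enrichment $FE = (s/b)/(k/N)$ (`enrich_gene_set()`,
`compare_enriched()`); and stability is quantified by the average
column-wise-maximum Jaccard under repeated random node deletion
(`robustness_run()`). The multi-seed protocol for stochastic methods
(10 seeds in $[0, 10000]$, keep the highest-Q run) is
`best_of_runs()`.

## Worked example

```r
library(bionetcomm)

fx  <- planted_partition_graph(sizes = rep(32, 4), p_in = 0.3,
                               p_out = 0.01, seed = 42)
ann <- synthetic_annotation(fx$truth, n_pathways = 12,
                            size_range = c(18, 28), purity = 0.9,
                            n_categories = 3, seed = 43)
report <- run_comparison(list(
  graph = fx$graph, methods = c("louvain", "spinglass"),
  seed = 1, runs = 10, min_size = 20,
  annotations = ann, min_count = 5, p_cutoff = 0.01))
print(report)
```

```
Community-comparison report
     method         q n_communities runtime_s
1   louvain 0.6485464             4     0.028
2 spinglass 0.6485464             4     0.354
most similar pair: louvain vs spinglass (RI 1.000, ARI 1.000, NMI 1.000)
```

Both methods find the four planted 32-node blocks (Q = 0.6485; the
agreement metrics are all 1, and `compare_partitions(...,
fx$truth)$ari` is 1 against the ground truth). The enrichment layer
then compares matched communities pathway by pathway:

```r
report$enrichment$similar[["louvain:1_vs_spinglass:1"]]
```

```
    pathway category count_a count_b common
 pathway_09     cat3      20      20     20
overall: 20 vs 20 enriched genes, 20 common -> 100 % overlap
```

i.e. the first matched community pair is enriched for the same pathway
with identical gene content — a 100% overlap by the
`common / max(sizes)` convention of `overlap_percent()`.

The numbered scripts under `analysis/` run the same flow at a larger
scale (400-node heterogeneous-degree networks, 10-seed protocols, 100
robustness repeats) and write their tables under `results/`.

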