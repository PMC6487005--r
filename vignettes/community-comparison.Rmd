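---
title: "Comparing community detection methods on biological networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing community detection methods on biological networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bionetcomm)
```

## The problem

Protein-protein interaction (PPI) networks carry thousands of nodes and
hundreds of thousands of interactions; biological interpretation only
becomes possible once the network is broken into communities — groups
of genes with denser connectivity inside than outside, which tend to
correspond to protein complexes, pathways and broad cellular functions.
Many detection algorithms exist, nearly all of them maximizing the same
objective in different ways, and they disagree in practice. This
package implements a full comparison pipeline: six detection
algorithms, partition-similarity metrics, Jaccard-based community
matching, hypergeometric pathway enrichment of matched communities, and
a node-deletion robustness analysis — together with generators for
planted-partition surrogates of PPI data, so every stage is exercisable
and testable without any database download.

## The objective: modularity

For an undirected graph with adjacency (weight) $A_{ij}$, degrees
$k_i$, and total edge weight $m$, the modularity of a partition
$\{c_i\}$ is

$$Q = \frac{1}{2m} \sum_{i,j}\left[A_{ij} -
  \frac{k_i k_j}{2m}\right]\delta(c_i, c_j),$$

the fraction of intra-community weight minus its expectation under the
degree-preserving null model. The sum runs over all ordered pairs
including $i = j$, so the single-community partition of *any* graph
scores exactly 0 and every partition of a complete graph scores $\le
0$. Internally `modularity_q()` evaluates the equivalent community form
$\sum_c (e_c/m - (d_c/2m)^2)$; a double-loop evaluator in the test
suite guards the equivalence.

The Potts spin-glass energy

$$\mathcal{H}(\{\sigma\}) = -\sum_{i \ne j}\left(A_{ij} -
  \gamma\,\frac{k_i k_j}{2m}\right)\delta(\sigma_i, \sigma_j)$$

rewards internal links and penalizes internal non-links. Because
$\mathcal{H}$ excludes the diagonal ($i \ne j$) while $Q$ includes it,
the exact relation at $\gamma = 1$ is

$$Q = -\frac{\mathcal{H}}{2m} - \sum_i \frac{k_i^2}{(2m)^2},$$

with a partition-independent correction term — minimizing
$\mathcal{H}$ and maximizing $Q$ therefore select the same partitions,
and the identity is asserted to $10^{-9}$ on random draws.

## The algorithms and their tunables

* **`girvan_newman()`** — divisive: repeatedly remove the edge of
  maximal shortest-path betweenness (recomputed after every removal;
  ties broken lexicographically for determinism) and cut the resulting
  dendrogram at maximal Q. $O(m^2 n)$; used on small networks only.
* **`fast_greedy()`** — agglomerative: maintain the pairwise merge
  gains $\Delta Q_{ij}$ of connected communities sparsely and always
  apply the best merge. The stored gains are kept at the scale of the
  *exact* modularity difference of the merge (for two connected
  singletons, $w_{ij}/m - 2a_ia_j$ with $a_i = k_i/2m$ — twice the
  half-scale initialization some presentations print, which the
  update rules $\Delta Q'_{jk} = \Delta Q_{ik} + \Delta Q_{jk}$ /
  $\Delta Q_{ik} - 2a_ja_k$ / $\Delta Q_{jk} - 2a_ia_k$ silently
  assume). This makes the recorded Q trajectory exact, which the test
  suite verifies after every merge; the arg-max behaviour is unchanged
  either way.
* **`louvain(seed, min_gain = 1e-7)`** — two phases per pass: local
  moves (seed-shuffled sweep order, exact gain
  $\Delta Q = (l_{i,B} - l_{i,A\setminus i})/m - k_i(K_B -
  K_{A\setminus i})/(2m^2)$, applied only when strictly positive) and
  aggregation into a weighted super-graph with self-loops. Passes stop
  when a pass improves Q by less than `min_gain`. The printed textbook
  gain formula does not equal the direct Q difference; the exact form
  is used so that every applied gain matches
  `modularity(after) - modularity(before)`, which a replay test
  enforces.
* **`leading_eigen(tol = 1e-10)`** — recursive spectral bisection of
  the modularity matrix $B_{ij} = A_{ij} - k_ik_j/2m$, restricted to
  the current group with the standard row-sum correction; a group is
  indivisible when its leading eigenvalue is $\le$ `tol` or the sign
  split does not increase Q. Recursive two-way splitting is used
  because no multi-way optimizer is specified for the index-matrix
  formulation.
* **`spinglass(gamma = 1, schedule, seed, sweeps_per_temp = 5)`** —
  single-node Metropolis updates cooling geometrically from
  `start_temp = 1` to `stop_temp = 0.01` with `cooling_factor = 0.99`
  and at most `spins = 25` states (igraph's defaults, which the study
  this reimplements found best); proposals favour neighboring
  communities with a 10% chance of a uniformly random spin so splits
  remain reachable. Requires a connected graph — disconnected parts
  share no energy terms, so their relative spin states are arbitrary;
  `detector()` restricts to the largest component by default.
* **`combo(seed, max_communities = Inf, n_intermediate = 2)`** — for
  every (source, destination-or-new) community pair, the best node
  repartition found by Kernighan-Lin switch series started from the
  original configuration, the full merger, and `n_intermediate` random
  intermediate subsets; the single best change is applied until no
  change improves Q. Two random intermediates is the package default
  (the count is unspecified in the source description).
* **`conclude(kappa = 20, phi = 10 m, seed)`** — estimates
  $\kappa$-path edge centralities by sampling `phi` seeded random
  simple paths (uniform among unvisited neighbors, length $\le
  \kappa$), converts them into endpoint distances $\sigma_{ij}$ (the
  three-term root-mean-square formula over exclusive and common
  neighbors, empty index sets contributing zero, each endpoint's
  partner excluded from its neighbor set), and runs Louvain on the
  network reweighted by $w_{ij} = 1/(1 + \sigma_{ij})$. How the
  distance matrix should feed the final clustering step is not
  specified by the method's description; the $1/(1+\sigma)$ similarity
  transform is this package's documented choice — monotone decreasing
  in the distance, bounded in $(0, 1]$, and exercised by the recovery
  tests.

`best_of_runs()` implements the multi-seed protocol used for the
stochastic methods: `n_runs = 10` seeds drawn without replacement from
$[0, 10000]$, every run's Q and community count recorded, the largest-Q
run kept (ties to the smallest seed).

## Comparing partitions

`compare_partitions()` returns the Rand index
$(n_{00}+n_{11})/\binom{N}{2}$, the chance-corrected adjusted Rand
index, and normalized mutual information $2I(A,B)/(H(A)+H(B))$, all
from the confusion matrix. NMI is computed in the count-consistent form
(any log base; natural log used) — the probability-scale numerator
sometimes printed next to a count-scale denominator is not a valid
normalization. Degenerate conventions: NMI of two single-block (or
otherwise zero-entropy) partitions is 1 when they are identical and 0
otherwise; ARI with a vanishing denominator is 1 exactly when the
partitions are identical. Both ARI and NMI are cross-checked against
independent implementations (mclust, igraph) in the tests.

Community-level matching uses `jaccard_matrix()` (intersection over
union, as a percentage, rows/columns sorted by decreasing size) over
communities with at least `min_size` nodes — 100 by default, matching
the convention that smaller communities rarely support pathway-level
interpretation. `match_communities()` picks each column's best row.
`overlap_percent()` encodes the reporting convention for "x% overlap"
between two matched gene sets: `common / max(size_a, size_b)`, rounded
half away from zero; this convention reproduces every printed instance
the package's tests assert, while `common/min` and Jaccard do not.

## Enrichment model

`enrich_gene_set()` scores a community against an `annotation_set()`
(pathway gene sets, optional broad categories, background universe of
size $N$). For a pathway with $b$ genes and a query with $k$ annotated
genes of which $s$ fall in the pathway: the one-sided hypergeometric
tail $P(X \ge s)$ (Fisher's exact test) and the fold enrichment
$FE = (s/b)/(k/N)$. Only genes inside the universe count towards $k$,
mirroring annotation services that cannot annotate every input. The
default filters retain pathways with `count > 10` and `p <= 0.01`
(both configurable; the filtering intentionally uses raw p-values to
match the study design, with Benjamini-Hochberg q-values reported
alongside). `category_composition()` pools unique genes per broad
category as a percentage of all enriched genes (shared genes count in
each category, so sums may exceed 100).
`pathway_community_distribution()` tabulates where each pathway's
genes land across communities with a significance flag per cell.
`map_orthologs()` applies a many-to-many ortholog relation to carry
communities across species.

## Robustness analysis

`robustness_run()` quantifies stability under perturbation: compute a
reference partition, then per repeat delete `round(fraction * n)`
random nodes (1% by default), re-detect, restrict the reference, and
take the average of column-wise maxima of the Jaccard matrix
(columns = restricted reference; the statistic is directional and the
argument order is asserted in tests). Per-repeat seeds derive
deterministically from the master seed. The size floor defaults to 100
nodes but must sit below the community scale to be meaningful: the
fixture-scale analyses (400-node networks with 100-node planted
blocks) use `min_size = 50`, because a floor of 100 silently discards
a 100-node reference block as soon as one of its nodes is deleted.
When a deletion disconnects the graph and the method requires
connectivity, the method runs on the largest component and the nodes
lost to disconnection are treated like deleted nodes for that repeat.

## What the generators emulate — and what they do not

`planted_partition_graph()` draws independent Bernoulli edges with
probability `p_in` inside blocks and `p_out` between them; with
`heterogeneous = TRUE`, lognormal ($\sigma = 1$, normalized to mean 1)
per-node propensities multiply into the pair probabilities (clipped at
1), reproducing the right-skewed degree distributions of real PPI
networks at approximately unchanged expected edge count.
`synthetic_annotation()` concentrates each pathway's genes in a home
block (`purity` = fraction drawn from it); `synthetic_ortholog_table()`
builds a partial many-to-many cross-species map with set coverage.

These surrogates capture what the pipeline's correctness depends on —
strong planted structure, degree skew, annotation-community
concordance, partial orthology — but not everything real data has: no
overlapping complexes, no correlated false-positive edges from
high-throughput screens, no power-law tail beyond lognormal skew, no
database-version effects. Passing tests therefore certify the
machinery (algorithms find planted optima, metrics and enrichment
compute what they claim), not that any particular biological network
will yield communities this clean; on real PPI snapshots, modularities
near 0.2-0.3 and partial method agreement are the norm rather than the
near-perfect recovery seen on the benchmarks.

## Numerical choices and problem sizes

Tie-breaks are deterministic throughout (lexicographic edge order in
the divisive algorithm, first-maximum elsewhere); all randomness flows
from one integer seed per call and never touches the caller's RNG
state. Zero-edge and empty-graph inputs are legal everywhere except
where connectivity is a stated precondition. The test suite sizes its
problems so the whole run stays in the tens of seconds: brute-force
enumeration oracles up to 8-node graphs (4140 partitions), bookkeeping
replays at 24-50 nodes, recovery benchmarks at 4 blocks of 32 nodes,
robustness at 4 blocks of 100; the analysis workflow under `analysis/`
uses 400-node networks with 100 repeats. These sizes are the package's
own choices for a fast, deterministic demonstration; every function
accepts larger inputs.

## Known limitations

The divisive algorithm is quadratic in edges and impractical beyond a
few thousand nodes (the reason it is excluded from the large-network
analysis stages). The spin-glass annealer is the slowest method per
run and its schedule is a heuristic: on large sparse networks more
sweeps per temperature may be needed for competitive Q. The
information-theoretic flow-compression method sometimes grouped with
these six is not implemented: its objective's sub-symbols are not
defined in the source material this package follows. Enrichment
assumes a fixed background universe; DAVID-style EASE corrections and
GO-hierarchy-aware term selection are out of scope.
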