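make_toy_annotation <- function() {
  universe <- paste0("g", 1:200)
  annotation_set(
    list(pw_a = paste0("g", 1:40),
         pw_b = paste0("g", 31:90),
         pw_c = paste0("g", 150:200)),
    category = c(pw_a = "M", pw_b = "M", pw_c = "CP"),
    universe = universe
  )
}

test_that("fold enrichment follows (s/b)/(k/N) and its identities", {
  ann <- make_toy_annotation()
  # query = entire universe: FE is exactly 1 for every pathway
  rows <- enrich_gene_set(ann$universe, ann, min_count = 0, p_cutoff = 1)
  expect_true(all(rows$fold_enrichment == 1))
  expect_true(all(rows$count == rows$b))

  # worked arithmetic: s=20, b=100, k=500, N=5000 -> FE = 2
  expect_equal((20 / 100) / (500 / 5000), 2)
  big <- annotation_set(list(pw = paste0("u", 1:100)),
                        universe = paste0("u", 1:5000))
  expect_error(enrich_gene_set(paste0("x", 1:5), big), "no genes")
  # genes outside the universe do not count towards k
  r <- enrich_gene_set(c(paste0("u", 1:20), "u600", paste0("x", 1:30)),
                       big, min_count = 0, p_cutoff = 1)
  expect_equal(r$k, 21)
  expect_equal(r$fold_enrichment, (20 / 100) / (21 / 5000))

  # FE unchanged when N and b double (property over random draws)
  for (seed in 1:20) {
    vals <- withr::with_seed(seed, {
      b <- sample(10:50, 1); N <- sample(500:2000, 1)
      k <- sample(50:200, 1); s <- sample(1:min(b, k), 1)
      c((s / b) / (k / N), (s / (2 * b)) / (k / (2 * N)))
    })
    expect_equal(vals[1], vals[2])
  }
})

test_that("hypergeometric p-values match exact combinatorial sums", {
  # worked example: all 5 pathway genes drawn in 5 picks from 20
  ann <- annotation_set(list(pw = paste0("g", 1:5)),
                        universe = paste0("g", 1:20))
  r <- enrich_gene_set(paste0("g", 1:5), ann, min_count = 0, p_cutoff = 1)
  expect_equal(r$p_value, 1 / choose(20, 5), tolerance = 1e-12)

  # exhaustive small-universe agreement with direct enumeration
  for (N in c(12, 20, 30)) {
    for (seed in 1:5) {
      draws <- withr::with_seed(seed + N, {
        b <- sample(2:(N - 2), 1)
        k <- sample(2:(N - 2), 1)
        s <- sample(0:min(b, k), 1)
        c(b = b, k = k, s = max(s, 1))
      })
      p_pkg <- stats::phyper(draws["s"] - 1, draws["b"],
                             N - draws["b"], draws["k"],
                             lower.tail = FALSE)
      expect_equal(unname(p_pkg),
                   exact_hyper_tail(draws["s"], draws["b"], draws["k"], N),
                   tolerance = 1e-12)
    }
  }
})

test_that("count and p-value filters prune and order the table", {
  ann <- make_toy_annotation()
  rows <- enrich_gene_set(paste0("g", 1:40), ann, min_count = 10,
                          p_cutoff = 0.01)
  expect_true(all(rows$count > 10))
  expect_true(all(rows$p_value <= 0.01))
  expect_true(!is.unsorted(rows$p_value))
  expect_true(all(rows$q_value >= rows$p_value))
})

test_that("enrichment comparison tabulates shared genes per pathway", {
  ann <- make_toy_annotation()
  ra <- enrich_gene_set(paste0("g", 1:45), ann, min_count = 5,
                        p_cutoff = 0.05)
  cmp_same <- compare_enriched(ra, ra)
  expect_true(all(cmp_same$per_pathway$common ==
                    cmp_same$per_pathway$count_a))
  expect_equal(cmp_same$overall$overlap_percent, 100)

  # a pathway enriched on one side only gets a zero column
  rb <- enrich_gene_set(paste0("g", 150:200), ann, min_count = 5,
                        p_cutoff = 0.05)
  cmp <- compare_enriched(ra, rb)
  only_a <- setdiff(ra$pathway, rb$pathway)
  expect_true(all(cmp$per_pathway$count_b[
    cmp$per_pathway$pathway %in% only_a] == 0))

  # overall overlap via the printed-count convention
  expect_equal(overlap_percent(406, 273, 239), 59)
})

test_that("category composition pools unique genes per broad category", {
  # three cellular-process pathways with 61, 46 and 63 genes pooling to
  # 159 unique genes out of 1136 total -> about 14 percent
  genes_cp <- list(paste0("c", 1:61), paste0("c", 50:95), paste0("c", 90:152))
  expect_equal(length(unique(unlist(genes_cp))), 152)
  rows <- data.frame(
    pathway = c("lyso", "perox", "phago", "other"),
    category = c("CP", "CP", "CP", "M"),
    stringsAsFactors = FALSE
  )
  rows$genes <- I(c(genes_cp, list(paste0("m", 1:984))))
  comp <- category_composition(rows)
  expect_equal(unname(comp["CP"]), 100 * 152 / 1136, tolerance = 1e-12)

  one <- rows[rows$category == "M", ]
  expect_equal(unname(category_composition(one)), 100)

  rows_bad <- rows
  rows_bad$category[1] <- NA
  expect_error(category_composition(rows_bad), "category")
})

test_that("pathway gene distribution localizes under pure annotations", {
  fx <- planted_partition_graph(c(60, 60, 60), 0.3, 0.01, seed = 11)
  ann <- synthetic_annotation(fx$truth, n_pathways = 9,
                              size_range = c(20, 35), purity = 1,
                              seed = 12)
  dist <- pathway_community_distribution(fx$truth, ann,
                                         min_count = 10, p_cutoff = 0.01)
  expect_equal(nrow(dist$counts), 9L)
  # purity 1: every pathway's genes land in exactly one community and
  # only that column is significant
  expect_true(all(rowSums(dist$counts > 0) == 1))
  expect_true(all(rowSums(dist$significant) == 1))
  expect_equal(unname(dist$total), unname(dist$b))
  expect_true(all(dist$total <= dist$b))
})

test_that("split pathways spread their counts symmetrically", {
  nodes <- paste0("g", 1:100)
  p <- partition(stats::setNames(rep(c("A", "B"), each = 50), nodes))
  ann <- annotation_set(list(split_pw = c(paste0("g", 1:20),
                                          paste0("g", 51:70))),
                        universe = nodes)
  dist <- pathway_community_distribution(p, ann, min_count = 10,
                                         p_cutoff = 1)
  expect_equal(unname(dist$counts[1, ]), c(20L, 20L))
})

test_that("ortholog mapping is a many-to-many relation image", {
  tab <- data.frame(source = c("a", "a", "b", "c"),
                    target = c("x", "y", "z", "x"))
  res <- map_orthologs(c("a", "b", "q"), tab)
  expect_setequal(res$mapped, c("x", "y", "z"))
  expect_equal(res$unmapped, 1L)

  empty <- map_orthologs(c("a", "b"), tab[0, ])
  expect_equal(empty$mapped, character(0))
  expect_equal(empty$unmapped, 2L)

  # bijective toy table: image is all five targets
  bij <- data.frame(source = paste0("s", 1:5), target = paste0("t", 1:5))
  expect_setequal(map_orthologs(paste0("s", 1:5), bij)$mapped,
                  paste0("t", 1:5))
})

test_that("GMT round-trip preserves pathways, categories and universe", {
  ann <- make_toy_annotation()
  gmt <- withr::local_tempfile(fileext = ".gmt")
  cats <- withr::local_tempfile(fileext = ".tsv")
  write_annotation_gmt(ann, gmt, cats)
  ann2 <- read_annotation_gmt(gmt, cats, universe = ann$universe)
  expect_equal(ann2$pathways, ann$pathways)
  expect_equal(ann2$category[names(ann$category)], ann$category)
  expect_setequal(ann2$universe, ann$universe)
  expect_error(annotation_set(list(pw = "zz"), universe = "aa"),
               "outside the universe")
})
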