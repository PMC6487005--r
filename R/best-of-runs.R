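#' Detector closures for the supported methods
#'
#' Returns a function `f(g, seed)` producing a [partition()], wrapping
#' one of the detection algorithms with fixed tuning parameters. This
#' is the interface consumed by [best_of_runs()], [robustness_run()]
#' and [run_comparison()]. Methods requiring connectivity (spinglass,
#' conclude) are run on the largest connected component when
#' `restrict_to_lcc` is `TRUE` (the default), and their partitions then
#' cover only that component.
#'
#' @param method One of `"girvan_newman"`, `"fast_greedy"`,
#'   `"louvain"`, `"leading_eigen"`, `"spinglass"`, `"combo"`,
#'   `"conclude"`.
#' @param restrict_to_lcc Restrict connectivity-requiring methods to
#'   the largest connected component (default `TRUE`).
#' @param ... Tuning parameters forwarded to the algorithm (e.g.
#'   `gamma`, `schedule`, `kappa`, `phi`, `min_gain`,
#'   `max_communities`).
#' @return A function of `(g, seed)`.
#' @export
detector <- function(method, restrict_to_lcc = TRUE, ...) {
  method <- match.arg(method, c("girvan_newman", "fast_greedy", "louvain",
                                "leading_eigen", "spinglass", "combo",
                                "conclude"))
  args <- list(...)
  needs_connected <- method %in% c("spinglass", "conclude")
  f <- switch(
    method,
    girvan_newman = function(g, seed) best_cut(girvan_newman(g))$partition,
    fast_greedy = function(g, seed) best_cut(fast_greedy(g))$partition,
    leading_eigen = function(g, seed)
      best_cut(do.call(leading_eigen, c(list(g), args)))$partition,
    louvain = function(g, seed)
      do.call(louvain, c(list(g, seed = seed), args)),
    spinglass = function(g, seed)
      do.call(spinglass, c(list(g, seed = seed), args)),
    combo = function(g, seed)
      do.call(combo, c(list(g, seed = seed), args)),
    conclude = function(g, seed)
      do.call(conclude, c(list(g, seed = seed), args))
  )
  out <- function(g, seed) {
    if (needs_connected && restrict_to_lcc && !is_connected_graph(g)) {
      g <- largest_component(g)
    }
    f(g, seed)
  }
  attr(out, "method") <- method
  attr(out, "stochastic") <-
    method %in% c("louvain", "spinglass", "combo", "conclude")
  out
}

#' Repeat a stochastic detector and keep the highest-modularity run
#'
#' Runs a detection method `n_runs` times with distinct seeds drawn
#' without replacement from `[seed_low, seed_high]`, records modularity
#' and community count per run, and returns the run with the largest Q
#' (ties broken by the smallest seed).
#'
#' @param method A detector closure from [detector()] (or any function
#'   of `(g, seed)` returning a [partition()]).
#' @param g The graph.
#' @param n_runs Number of runs (>= 1), default 10.
#' @param seed_low,seed_high Inclusive seed range to draw from
#'   (defaults 0 and 10000).
#' @param seed Master seed controlling which run seeds are drawn.
#' @return A list with `best` (list `method`, `partition`, `q`, `seed`,
#'   `runtime_s`) and `runs` (data frame with one row per run:
#'   `method`, `seed`, `q`, `n_communities`, `runtime_s`).
#' @export
best_of_runs <- function(method, g, n_runs = 10L, seed_low = 0L,
                         seed_high = 10000L, seed = 1L) {
  stopifnot(n_runs >= 1L, seed_high - seed_low + 1L >= n_runs)
  method_name <- attr(method, "method")
  if (is.null(method_name)) {
    method_name <- "custom"
  }
  seeds <- with_seed(seed, {
    seed_low + sample.int(seed_high - seed_low + 1L, n_runs) - 1L
  })
  rows <- vector("list", n_runs)
  parts <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    t0 <- proc.time()[["elapsed"]]
    p <- method(g, seeds[r])
    dt <- proc.time()[["elapsed"]] - t0
    gq <- if (setequal(names(p$membership), igraph::V(g)$name)) g else {
      igraph::induced_subgraph(g, names(p$membership))
    }
    parts[[r]] <- p
    rows[[r]] <- data.frame(
      method = method_name, seed = seeds[r], q = modularity_q(gq, p),
      n_communities = n_communities(p), runtime_s = dt
    )
  }
  runs <- do.call(rbind, rows)
  ord <- order(-runs$q, runs$seed)
  b <- ord[1L]
  list(
    best = list(method = method_name, partition = parts[[b]],
                q = runs$q[b], seed = runs$seed[b],
                runtime_s = runs$runtime_s[b]),
    runs = runs
  )
}
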