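#' Potts spin-glass Hamiltonian of a partition
#'
#' Evaluates
#' \deqn{\mathcal{H}(\{\sigma\}) = -\sum_{i \ne j}
#'   \left(A_{ij} - \gamma \frac{k_i k_j}{2m}\right)
#'   \delta(\sigma_i, \sigma_j)}
#' over ordered node pairs with \eqn{i \ne j}: internal links lower the
#' energy, internal non-links raise it through the null-model term. At
#' \eqn{\gamma = 1} the identity
#' \eqn{Q = -\mathcal{H}/(2m) - \sum_i k_i^2/(2m)^2}
#' links the energy to modularity; the correction term is the
#' partition-independent diagonal of the modularity sum, so minimizing
#' \eqn{\mathcal{H}} and maximizing Q select the same partitions.
#'
#' @param g An undirected simple graph.
#' @param p A [partition()] covering the nodes of `g`.
#' @param gamma Relative weight of the null-model (non-link) term,
#'   default 1.
#' @return The Hamiltonian value.
#' @export
hamiltonian <- function(g, p, gamma = 1) {
  memb <- membership_for_graph(g, p)
  gi <- graph_index(g)
  hamiltonian_from_index(gi, memb, gamma)
}

hamiltonian_from_index <- function(gi, memb, gamma) {
  if (gi$n == 0L) {
    return(0)
  }
  # link term: 2 * sum of intra-community edge weights
  cf <- memb[gi$edges[, 1L]]
  ct <- memb[gi$edges[, 2L]]
  link <- 2 * sum(gi$edge_w[cf == ct])
  if (gi$m == 0) {
    return(-link)
  }
  # null term: gamma/2m * (sum_c K_c^2 - sum_i k_i^2)  (i != j only)
  K_c <- tapply(gi$deg, memb, sum)
  null <- gamma * (sum(K_c^2) - sum(gi$deg^2)) / (2 * gi$m)
  -(link - null)
}

#' Annealing schedule for the spin-glass search
#'
#' @param start_temp,stop_temp Positive start and stop temperatures,
#'   `stop_temp < start_temp`.
#' @param cooling_factor Multiplicative cooling per temperature step,
#'   strictly in (0, 1).
#' @param spins Maximum number of spin states (communities), >= 2.
#' @return A list of class `annealing_schedule`.
#' @export
annealing_schedule <- function(start_temp = 1, stop_temp = 0.01,
                               cooling_factor = 0.99, spins = 25L) {
  stopifnot(start_temp > 0, stop_temp > 0, stop_temp < start_temp,
            cooling_factor > 0, cooling_factor < 1, spins >= 2)
  structure(list(start_temp = start_temp, stop_temp = stop_temp,
                 cooling_factor = cooling_factor, spins = as.integer(spins)),
            class = "annealing_schedule")
}

#' Spin-glass community detection by simulated annealing
#'
#' Minimizes the Potts [hamiltonian()] over spin configurations with at
#' most `spins` states using single-node Metropolis updates: at each
#' temperature, `sweeps_per_temp * n` proposals move a random node to a
#' spin drawn from its neighboring communities or (occasionally) a
#' uniformly random spin state, accepted when the energy decreases or
#' with probability \eqn{\exp(-\Delta\mathcal{H}/T)}. The temperature
#' cools geometrically from `start_temp` to `stop_temp`. The
#' lowest-energy configuration encountered is returned. The search is
#' stochastic but fully reproducible from `seed`.
#'
#' The method requires a connected graph: nodes in different components
#' share no energy terms beyond the null model, so their relative spin
#' states are not meaningfully determined.
#'
#' @param g A connected undirected simple graph.
#' @param gamma Null-model weight (default 1).
#' @param schedule An [annealing_schedule()].
#' @param seed Integer seed.
#' @param sweeps_per_temp Proposal sweeps per temperature step
#'   (default 5).
#' @return A [partition()] of the nodes of `g`.
#' @export
spinglass <- function(g, gamma = 1, schedule = annealing_schedule(),
                      seed = 0L, sweeps_per_temp = 5L) {
  if (!is_connected_graph(g)) {
    stop("spinglass requires a connected graph: nodes in disconnected ",
         "parts have no determined relative spin states; run on one ",
         "component (see connected_components())")
  }
  gi <- graph_index(g)
  n <- gi$n
  if (n == 0L) {
    return(partition(stats::setNames(character(0), character(0))))
  }
  q_spins <- min(schedule$spins, n)
  with_seed(seed, {
    memb <- sample.int(q_spins, n, replace = TRUE)
    K <- numeric(q_spins)
    agg <- rowsum(gi$deg, memb)
    K[as.integer(rownames(agg))] <- agg[, 1L]
    two_m <- 2 * gi$m
    h_cur <- hamiltonian_from_index(gi, memb, gamma)
    h_best <- h_cur
    memb_best <- memb
    temp <- schedule$start_temp
    while (temp > schedule$stop_temp) {
      for (rep in seq_len(sweeps_per_temp)) {
        nodes <- sample.int(n, n, replace = TRUE)
        pick_new <- stats::runif(n) < 0.1
        rand_spin <- sample.int(q_spins, n, replace = TRUE)
        accept_u <- stats::runif(n)
        for (t in seq_len(n)) {
          i <- nodes[t]
          a <- memb[i]
          nb <- gi$adj[[i]]
          if (length(nb) == 0L) next
          if (pick_new[t]) {
            b <- rand_spin[t]
          } else {
            b <- memb[nb[1L + (rand_spin[t] %% length(nb))]]
          }
          if (b == a) next
          w_nb <- gi$adj_w[[i]]
          mnb <- memb[nb]
          l_ia <- sum(w_nb[mnb == a])
          l_ib <- sum(w_nb[mnb == b])
          # energy change of moving i from spin a to spin b
          dh <- 2 * ((l_ia - gamma * gi$deg[i] * (K[a] - gi$deg[i]) / two_m) -
                       (l_ib - gamma * gi$deg[i] * K[b] / two_m))
          if (dh < 0 || accept_u[t] < exp(-dh / temp)) {
            memb[i] <- b
            K[a] <- K[a] - gi$deg[i]
            K[b] <- K[b] + gi$deg[i]
            h_cur <- h_cur + dh
            if (h_cur < h_best - 1e-12) {
              h_best <- h_cur
              memb_best <- memb
            }
          }
        }
      }
      temp <- temp * schedule$cooling_factor
    }
    partition_from_membership(g, compact_labels(memb_best))
  })
}
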