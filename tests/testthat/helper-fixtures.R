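# Shared fixtures and independent oracles.

# Parameter set with every distribution collapsed to a point mass at its
# analytic mean: the degenerate PSA should then reproduce the base case in
# every iteration.
degenerate_parameter_set <- function(ps = load_parameters()) {
  to_point <- function(x) {
    if (inherits(x, "fitted_dist")) return(dist_point(as.numeric(dist_mean(x))))
    if (is.list(x)) return(lapply(x, to_point))
    x
  }
  for (sec in c("cure", "pathway", "costs", "utilities"))
    ps[[sec]] <- to_point(ps[[sec]])
  ps$accuracy$bwt_sensitivity <- to_point(ps$accuracy$bwt_sensitivity)
  ps$accuracy$bwt_specificity <- to_point(ps$accuracy$bwt_specificity)
  ps$accuracy$history_mixed_given <-
    lapply(ps$accuracy$history_mixed_given,
           function(d) dist_point(dist_mean(d)[["mixed"]]))
  ps$prevalence <- dist_point(as.numeric(dist_mean(ps$prevalence)))
  ps
}

# Brute-force cost-effectiveness frontier: strict pairwise dominance, then
# a greedy minimum-ICER climb from the cheapest strategy. Independent of
# the package's removal-loop implementation.
oracle_frontier_status <- function(cost, effect) {
  n <- length(cost)
  status <- rep("on_frontier", n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && cost[j] <= cost[i] && effect[j] >= effect[i] &&
          (cost[j] < cost[i] || effect[j] > effect[i])) {
        status[i] <- "dominated"
        break
      }
    }
  }
  nd <- which(status == "on_frontier")
  ord <- nd[order(cost[nd])]
  cur <- ord[1]
  frontier_set <- cur
  repeat {
    cand <- ord[effect[ord] > effect[cur]]
    if (!length(cand)) break
    ic <- (cost[cand] - cost[cur]) / (effect[cand] - effect[cur])
    nxt <- cand[which.min(ic)]
    frontier_set <- c(frontier_set, nxt)
    cur <- nxt
  }
  status[setdiff(nd, frontier_set)] <- "extended_dominated"
  status
}

# Hand-made psa_samples object for enumeration-oracle tests.
toy_psa_samples <- function(cost, qalys = NULL, p_success = NULL,
                            strategies = colnames(cost)) {
  n <- nrow(cost)
  if (is.null(qalys)) qalys <- matrix(0, n, ncol(cost))
  if (is.null(p_success)) p_success <- matrix(0, n, ncol(cost))
  colnames(cost) <- colnames(qalys) <- colnames(p_success) <- strategies
  structure(list(strategies = strategies, n_iterations = n, seed = 0L,
                 cost = cost, qalys = qalys, p_success = p_success,
                 theta = NULL,
                 econ = list(incidence_per_year = 54000,
                             research_horizon_years = 10, rate = 0.035)),
            class = "psa_samples")
}

# Analytic sd of a flat parameter's sampling distribution (for 3-SE
# Monte Carlo consistency checks).
analytic_sd <- function(d) {
  switch(d$kind,
    beta = {
      a <- d$params$alpha; b <- d$params$beta
      sqrt(a * b / ((a + b)^2 * (a + b + 1)))
    },
    gamma = sqrt(d$params$shape) * d$params$scale,
    point = 0,
    dirichlet = {
      a <- d$params$concentrations; a0 <- sum(a)
      sqrt(a * (a0 - a) / (a0^2 * (a0 + 1)))
    })
}
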