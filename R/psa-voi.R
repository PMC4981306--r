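# Probabilistic sensitivity analysis and value-of-information analysis.

#' Draw a joint parameter sample for the PSA
#'
#' One column per iteration, one row per flat model parameter. Every
#' parameter (or Dirichlet block) has its own random sub-stream seeded
#' deterministically from `seed`, so increasing `n` extends each stream
#' without altering earlier draws, and all strategies share the same joint
#' draw within an iteration.
#'
#' @param ps A `parameter_set`.
#' @param n Number of iterations.
#' @param seed Integer seed.
#' @return Numeric matrix (parameters x iterations) with rownames from the
#'   flat parameter vocabulary.
#' @export
sample_parameter_matrix <- function(ps, n, seed = 1L) {
  stopifnot(inherits(ps, "parameter_set"), n >= 1)
  fl <- flatten_parameters(ps)
  units <- c(names(fl$dists),
             unlist(lapply(fl$groups, function(g) g$members)))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  useeds <- sample.int(.Machine$integer.max - 1L, length(units))
  names(useeds) <- units

  nm <- flat_param_names()
  theta <- matrix(NA_real_, length(nm), n, dimnames = list(nm, NULL))
  for (u in names(fl$dists)) {
    d <- fl$dists[[u]]
    set.seed(useeds[[u]])
    theta[u, ] <- if (d$kind == "point") rep(d$params$value[1], n)
                  else dist_sample(d, n)
  }
  for (g in fl$groups) {
    if (g$dist$kind == "point") {
      theta[g$members, ] <- matrix(g$dist$params$value,
                                   length(g$members), n)
      next
    }
    conc <- g$dist$params$concentrations
    draws <- matrix(NA_real_, length(g$members), n)
    for (k in seq_along(g$members)) {
      set.seed(useeds[[g$members[k]]])
      draws[k, ] <- stats::rgamma(n, shape = conc[[k]], rate = 1)
    }
    theta[g$members, ] <- sweep(draws, 2, colSums(draws), "/")
  }
  if (anyNA(theta)) stop("incomplete parameter sample")
  theta
}

#' Run the probabilistic sensitivity analysis
#'
#' Monte Carlo propagation of parameter uncertainty: per iteration one
#' joint draw of all parameters (Beta for probabilities and utilities,
#' Gamma for costs, Dirichlet for multinomial splits), on which every
#' strategy tree is evaluated, so per-iteration outcomes are perfectly
#' coupled across strategies.
#'
#' @param ps A `parameter_set`.
#' @param strategies Strategies to evaluate (default all seven).
#' @param n_iterations Number of iterations (default the configured
#'   10,000).
#' @param seed Integer seed; identical seeds give identical results, and a
#'   subset of strategies reproduces its columns exactly.
#' @param chunk_size Iterations evaluated per block (memory control).
#' @return A `psa_samples` object: matrices `cost`, `qalys`, `p_success`
#'   (iterations x strategies), the parameter draws `theta`, and metadata.
#' @export
run_psa <- function(ps, strategies = strategy_ids(),
                    n_iterations = NULL, seed = 1L, chunk_size = 1000L) {
  stopifnot(inherits(ps, "parameter_set"))
  n <- as.integer(n_iterations %||% ps$econ$psa_iterations %||% 10000L)
  stopifnot(n >= 1L)
  theta <- sample_parameter_matrix(ps, n, seed)
  comps <- lapply(strategies, function(s)
    compile_tree(build_strategy_tree(s, ps)))
  S <- length(strategies)
  cost <- qalys <- psucc <- matrix(NA_real_, n, S,
                                   dimnames = list(NULL, strategies))
  starts <- seq(1L, n, by = chunk_size)
  for (s0 in starts) {
    s1 <- min(s0 + chunk_size - 1L, n)
    th <- theta[, s0:s1, drop = FALSE]
    for (k in seq_len(S)) {
      o <- compiled_outcomes(comps[[k]], th)
      cost[s0:s1, k] <- o$cost
      qalys[s0:s1, k] <- o$qalys
      psucc[s0:s1, k] <- o$p_success
    }
  }
  structure(list(strategies = strategies, n_iterations = n, seed = seed,
                 cost = cost, qalys = qalys, p_success = psucc,
                 theta = theta, econ = extract_econ(ps)),
            class = "psa_samples")
}

#' @export
print.psa_samples <- function(x, ...) {
  cat("<psa_samples>", x$n_iterations, "iterations x",
      length(x$strategies), "strategies (seed", paste0(x$seed, ")\n"))
  m <- data.frame(strategy = x$strategies,
                  mean_cost = colMeans(x$cost),
                  mean_qalys = colMeans(x$qalys),
                  mean_p_success = colMeans(x$p_success))
  print(m, row.names = FALSE, digits = 4)
  invisible(x)
}

effect_matrix <- function(samples, effect = c("qalys", "p_success")) {
  effect <- match.arg(effect)
  samples[[effect]]
}

#' Cost-effectiveness acceptability frontier
#'
#' At each willingness-to-pay value the optimal strategy is the one with
#' the highest mean net monetary benefit across iterations ("determined
#' from the average results"); the frontier reports the probability that
#' this strategy attains the maximal net monetary benefit within an
#' iteration (ties split equally).
#'
#' @param samples A `psa_samples` object.
#' @param wtp_grid Numeric vector of willingness-to-pay thresholds (GBP per
#'   unit effect).
#' @param effect `"qalys"` or `"p_success"`.
#' @return A `ceaf_curve` data frame: `wtp`, `optimal`, `probability`.
#' @export
ceaf <- function(samples, wtp_grid, effect = c("qalys", "p_success")) {
  stopifnot(inherits(samples, "psa_samples"))
  if (!length(wtp_grid)) stop("`wtp_grid` must be nonempty")
  eff <- effect_matrix(samples, effect)
  out <- data.frame(wtp = wtp_grid, optimal = NA_character_,
                    probability = NA_real_)
  for (i in seq_along(wtp_grid)) {
    b <- nmb(samples$cost, eff, wtp_grid[i])
    opt <- which.max(colMeans(b))
    rmax <- do.call(pmax, as.data.frame(b))
    is_max <- b == rmax
    w <- is_max[, opt] / rowSums(is_max)
    out$optimal[i] <- samples$strategies[opt]
    out$probability[i] <- mean(w)
  }
  structure(out, class = c("ceaf_curve", "data.frame"),
            effect = match.arg(effect))
}

#' Per-person expected value of perfect information
#'
#' The expected opportunity loss of deciding under current uncertainty:
#' mean over iterations of the maximal net monetary benefit, minus the
#' maximum over strategies of the mean net monetary benefit. Tiny negative
#' floating-point residues are clipped at zero.
#'
#' @inheritParams ceaf
#' @param wtp Willingness-to-pay threshold (GBP per unit effect).
#' @return Per-person EVPI (GBP, non-negative).
#' @export
evpi_per_person <- function(samples, wtp, effect = c("qalys", "p_success")) {
  stopifnot(inherits(samples, "psa_samples"))
  eff <- effect_matrix(samples, effect)
  b <- nmb(samples$cost, eff, wtp)
  v <- mean(do.call(pmax, as.data.frame(b))) - max(colMeans(b))
  max(v, 0)
}

#' Population expected value of perfect information
#'
#' Scales the per-person EVPI by the yearly incident population over the
#' years research is expected to stay useful, discounted annually (first
#' year undiscounted).
#'
#' @param per_person Per-person EVPI (GBP).
#' @param incidence_per_year Incident women per year (base case 54,000).
#' @param years Years research remains useful (base case 10).
#' @param rate Annual discount rate (base case 0.035).
#' @return Population EVPI (GBP).
#' @examples
#' population_evpi(1, 54000, 10, 0.035)  # 54,000 x 8.6077
#' @export
population_evpi <- function(per_person, incidence_per_year, years, rate) {
  stopifnot(per_person >= 0, incidence_per_year > 0, years >= 1)
  per_person * incidence_per_year * sum((1 + rate)^-(seq_len(years) - 1L))
}

#' EVPI across a willingness-to-pay grid
#'
#' @inheritParams ceaf
#' @param incidence_per_year,years,rate Population-scaling settings;
#'   defaults from the samples' economic settings.
#' @return An `evpi_curve` data frame: `wtp`, `evpi` (per person),
#'   `pop_evpi`.
#' @export
evpi_curve <- function(samples, wtp_grid, effect = c("qalys", "p_success"),
                       incidence_per_year = NULL, years = NULL, rate = NULL) {
  stopifnot(inherits(samples, "psa_samples"))
  inc <- incidence_per_year %||% samples$econ$incidence_per_year
  yrs <- years %||% samples$econ$research_horizon_years
  r <- rate %||% samples$econ$rate
  ev <- vapply(wtp_grid, function(l) evpi_per_person(samples, l, effect),
               numeric(1))
  structure(data.frame(wtp = wtp_grid, evpi = ev,
                       pop_evpi = vapply(ev, population_evpi, numeric(1),
                                         incidence_per_year = inc,
                                         years = yrs, rate = r)),
            class = c("evpi_curve", "data.frame"), effect = match.arg(effect))
}

#' @export
plot.ceaf_curve <- function(x, ...) {
  graphics::plot(x$wtp, x$probability, type = "l", ylim = c(0, 1),
                 xlab = "Willingness to pay (GBP per unit effect)",
                 ylab = "P(optimal strategy cost-effective)",
                 main = "Cost-effectiveness acceptability frontier", ...)
  sw <- which(x$optimal[-1] != x$optimal[-nrow(x)])
  if (length(sw)) graphics::abline(v = x$wtp[sw + 1], lty = 3)
  invisible(x)
}

#' @export
plot.evpi_curve <- function(x, population = TRUE, ...) {
  y <- if (population) x$pop_evpi else x$evpi
  graphics::plot(x$wtp, y, type = "l",
                 xlab = "Willingness to pay (GBP per unit effect)",
                 ylab = if (population) "Population EVPI (GBP)" else
                   "Per-person EVPI (GBP)",
                 main = "Expected value of perfect information", ...)
  invisible(x)
}
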