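# Tree evaluation: expected-value rollback, exhaustive path enumeration,
# and a compiled sparse-path representation reused by the PSA.

eval_factor <- function(f, theta) {
  v <- f$a + if (length(f$ref)) sum(f$b * theta[f$ref]) else 0
  max(v, 0)
}

eval_prob <- function(prob, theta) {
  prod(vapply(prob, eval_factor, numeric(1), theta = theta))
}

eval_costs <- function(costs, theta) {
  if (!length(costs)) return(0)
  sum(vapply(costs, function(cc) cc$coef * theta[[cc$ref]], numeric(1)))
}

# QALY stream of a terminal node as coefficients on the utility parameters:
# the true-condition utility up to the year before cure, the cured utility
# (with or without side effects) from the cure year to the horizon
leaf_qaly_coefs <- function(leaf, econ) {
  D <- discount_factor(seq_len(econ$horizon), econ$rate)
  cond <- util_ref(leaf$condition)
  out <- numeric(0)
  if (is.na(leaf$cure_year)) {
    out[cond] <- sum(D)
  } else {
    yc <- leaf$cure_year
    cured <- if (leaf$side_effects) "util_cured_se" else "util_cured"
    if (yc > 1) out[cond] <- sum(D[seq_len(yc - 1L)])
    out[cured] <- sum(D[yc:econ$horizon])
  }
  out
}

#' Expected outcome of a strategy tree
#'
#' Recursive expected-value rollback of discounted cost, discounted QALYs
#' and the probability of successful treatment (subjective cure), with the
#' flat parameter values substituted into the branch probabilities. Agrees
#' with probability-weighted aggregation over [enumerate_paths()] to within
#' numerical precision.
#'
#' @param tree A `strategy_tree` from [build_strategy_tree()].
#' @param params A `point_parameters` (or `parameter_set`, collapsed via
#'   [point_estimates()]), or a named numeric vector of flat parameters.
#' @return A `strategy_outcome`: list with `cost`, `qalys`, `p_success`.
#' @export
evaluate <- function(tree, params) {
  theta <- as_theta(params)
  econ <- attr(tree, "econ")
  roll <- function(node) {
    if (node$kind == "terminal") {
      q <- leaf_qaly_coefs(node, econ)
      return(c(cost = 0, qalys = sum(q * theta[names(q)]),
               p_success = as.numeric(!is.na(node$cure_year))))
    }
    acc <- c(cost = 0, qalys = 0, p_success = 0)
    ptot <- 0
    for (b in node$branches) {
      pb <- eval_prob(b$prob, theta)
      ptot <- ptot + pb
      if (pb == 0) next
      v <- roll(b$child)
      acc <- acc + pb * c(v[["cost"]] + eval_costs(b$costs, theta),
                          v[["qalys"]], v[["p_success"]])
    }
    if (abs(ptot - 1) > 1e-6)
      stop("branch probabilities at node '", node$label,
           "' sum to ", format(ptot), " after substitution")
    acc
  }
  v <- roll(tree)
  structure(list(cost = v[["cost"]], qalys = v[["qalys"]],
                 p_success = v[["p_success"]],
                 strategy = attr(tree, "strategy")),
            class = "strategy_outcome")
}

#' @export
print.strategy_outcome <- function(x, ...) {
  cat(sprintf("%s: cost £%.0f | QALYs %.3f | P(success) %.3f\n",
              x$strategy %||% "strategy", x$cost, x$qalys, x$p_success))
  invisible(x)
}

as_theta <- function(params) {
  if (inherits(params, "parameter_set")) params <- point_estimates(params)
  if (inherits(params, "point_parameters")) return(params$values)
  if (is.numeric(params) && !is.null(names(params))) return(params)
  stop("`params` must be a parameter_set, point_parameters, or named vector")
}

#' Enumerate all root-to-leaf paths of a strategy tree
#'
#' The exhaustive-aggregation oracle for [evaluate()]: every path with its
#' probability, discounted cost, discounted QALYs, cure flag and event
#' trace. Path probabilities sum to one.
#'
#' @inheritParams evaluate
#' @return Data frame with columns `probability`, `discounted_cost`,
#'   `discounted_qalys`, `cured`, `trace`.
#' @export
enumerate_paths <- function(tree, params) {
  theta <- as_theta(params)
  econ <- attr(tree, "econ")
  rows <- list()
  walk <- function(node, prob, cost, trace, depth) {
    if (depth > 200L) stop("cycle detected: path depth exceeds 200")
    if (node$kind == "terminal") {
      q <- leaf_qaly_coefs(node, econ)
      rows[[length(rows) + 1L]] <<- data.frame(
        probability = prob, discounted_cost = cost,
        discounted_qalys = sum(q * theta[names(q)]),
        cured = !is.na(node$cure_year),
        trace = paste(c(trace, node$label), collapse = " > "),
        stringsAsFactors = FALSE)
      return()
    }
    for (b in node$branches) {
      walk(b$child, prob * eval_prob(b$prob, theta),
           cost + eval_costs(b$costs, theta),
           c(trace, b$label), depth + 1L)
    }
  }
  walk(tree, 1, 0, character(0), 0L)
  do.call(rbind, rows)
}

#' QALYs accrued over a tiled timeline of health states
#'
#' Sums utility x discounted duration over consecutive whole-year
#' segments: the first model year is undiscounted, later years carry the
#' annual discount. Segments must tile years `1..horizon` exactly.
#'
#' @param timeline Data frame with columns `state`, `start_year`,
#'   `end_year` (inclusive integer years).
#' @param utilities Named numeric vector mapping each state to its utility
#'   weight.
#' @param econ List with `horizon_years` and `discount_rate` (a
#'   `parameter_set$econ` works).
#' @return Discounted QALY total.
#' @examples
#' accrue_qalys(data.frame(state = "cured", start_year = 1, end_year = 5),
#'              c(cured = 1), list(horizon_years = 5, discount_rate = 0))
#' @export
accrue_qalys <- function(timeline, utilities, econ) {
  H <- as.integer(econ$horizon_years %||% econ$horizon)
  rate <- econ$discount_rate %||% econ$rate
  stopifnot(all(c("state", "start_year", "end_year") %in% names(timeline)))
  yrs <- unlist(Map(seq, timeline$start_year, timeline$end_year))
  if (anyDuplicated(yrs)) stop("overlapping timeline segments")
  if (!setequal(yrs, seq_len(H)))
    stop("timeline must tile years 1..", H, " exactly")
  D <- discount_factor(seq_len(H), rate)
  total <- 0
  for (i in seq_len(nrow(timeline))) {
    u <- utilities[[as.character(timeline$state[i])]]
    if (is.null(u) || is.na(u))
      stop("no utility for state: ", timeline$state[i])
    total <- total + u * sum(D[timeline$start_year[i]:timeline$end_year[i]])
  }
  total
}

#' Evaluate several strategies on one parameter set
#'
#' @param params A `parameter_set` or `point_parameters`.
#' @param strategies Character vector of [strategy_ids()].
#' @return Data frame: `strategy`, `cost`, `qalys`, `p_success`.
#' @examples
#' \donttest{
#' evaluate_strategies(load_parameters(),
#'                     c("uds_all", "history_all", "ultrasound_all"))
#' }
#' @export
evaluate_strategies <- function(params, strategies = strategy_ids()) {
  if (inherits(params, "parameter_set")) params <- point_estimates(params)
  rows <- lapply(strategies, function(s) {
    v <- evaluate(build_strategy_tree(s, params), params)
    data.frame(strategy = s, cost = v$cost, qalys = v$qalys,
               p_success = v$p_success, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# -- compiled sparse-path representation (shared by the PSA) ---------------

compile_tree <- function(tree) {
  econ <- attr(tree, "econ")
  pnames <- flat_param_names()
  pidx <- stats::setNames(seq_along(pnames), pnames)

  fa <- numeric(0)          # constant term per factor
  flong_fid <- integer(0)   # factor id per linear term
  flong_ref <- integer(0)   # parameter index per linear term
  flong_b <- numeric(0)     # coefficient per linear term
  fpath <- integer(0)       # path id per factor
  ctrip <- list(i = integer(0), j = integer(0), x = numeric(0))
  qtrip <- list(i = integer(0), j = integer(0), x = numeric(0))
  cured <- logical(0)
  npaths <- 0L

  walk <- function(node, factors, costs) {
    if (node$kind == "terminal") {
      npaths <<- npaths + 1L
      id <- npaths
      for (f in factors) {
        fa[[length(fa) + 1L]] <<- f$a
        fid <- length(fa)
        fpath[[fid]] <<- id
        if (length(f$ref)) {
          flong_fid <<- c(flong_fid, rep(fid, length(f$ref)))
          flong_ref <<- c(flong_ref, pidx[f$ref])
          flong_b <<- c(flong_b, f$b)
        }
      }
      if (length(costs)) {
        agg <- tapply(vapply(costs, `[[`, numeric(1), "coef"),
                      vapply(costs, `[[`, character(1), "ref"), sum)
        ctrip$i <<- c(ctrip$i, rep(id, length(agg)))
        ctrip$j <<- c(ctrip$j, pidx[names(agg)])
        ctrip$x <<- c(ctrip$x, as.numeric(agg))
      }
      q <- leaf_qaly_coefs(node, econ)
      qtrip$i <<- c(qtrip$i, rep(id, length(q)))
      qtrip$j <<- c(qtrip$j, pidx[names(q)])
      qtrip$x <<- c(qtrip$x, as.numeric(q))
      cured[[id]] <<- !is.na(node$cure_year)
      return()
    }
    for (b in node$branches)
      walk(b$child, c(factors, b$prob), c(costs, b$costs))
  }
  walk(tree, list(), list())

  list(n_paths = npaths, n_params = length(pnames), param_names = pnames,
       fa = fa, fpath = fpath,
       flong_fid = flong_fid, flong_ref = flong_ref, flong_b = flong_b,
       C = Matrix::sparseMatrix(i = ctrip$i, j = ctrip$j, x = ctrip$x,
                                dims = c(npaths, length(pnames))),
       Q = Matrix::sparseMatrix(i = qtrip$i, j = qtrip$j, x = qtrip$x,
                                dims = c(npaths, length(pnames))),
       cured = cured, econ = econ, strategy = attr(tree, "strategy"))
}

# Evaluate a compiled tree on a matrix of parameter draws (params x iters).
# Returns per-iteration expected cost, QALYs and cure probability.
compiled_outcomes <- function(comp, theta) {
  stopifnot(is.matrix(theta), nrow(theta) == comp$n_params)
  m <- ncol(theta)
  fv <- matrix(comp$fa, length(comp$fa), m)
  if (length(comp$flong_fid)) {
    contrib <- comp$flong_b * theta[comp$flong_ref, , drop = FALSE]
    agg <- rowsum(contrib, comp$flong_fid)
    rows <- as.integer(rownames(agg))
    fv[rows, ] <- fv[rows, , drop = FALSE] + agg
  }
  fv[fv < 0] <- 0  # guard: rare joint draws can push a residual below zero
  lp <- rowsum(log(fv), comp$fpath)
  p <- exp(lp)
  cp <- as.matrix(comp$C %*% theta)
  qp <- as.matrix(comp$Q %*% theta)
  list(cost = colSums(p * cp), qalys = colSums(p * qp),
       p_success = colSums(p[comp$cured, , drop = FALSE]),
       total_prob = colSums(p))
}
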