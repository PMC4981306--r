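#' Discount factor on the model's yearly grid
#'
#' Costs and QALYs accruing beyond 12 months are discounted at an annual
#' rate (3.5% in the base case): year 1 is undiscounted and year t >= 2
#' carries weight (1 + rate)^-(t - 1). Year 0 is treated as year 1
#' (model entry).
#'
#' @param year Integer year(s) >= 0.
#' @param rate Annual discount rate in `[0, 1)`.
#' @return Numeric discount factor(s), non-increasing in `year`.
#' @examples
#' discount_factor(1, 0.035)  # 1
#' discount_factor(2, 0.035)  # 1/1.035
#' @export
discount_factor <- function(year, rate) {
  if (any(year < 0)) stop("`year` must be >= 0")
  stopifnot(rate >= 0, rate < 1)
  ifelse(year <= 1, 1, (1 + rate)^-(year - 1))
}

#' Net monetary benefit
#'
#' `wtp * effect - cost`: positive when the effect is worth more than it
#' costs at the stated willingness-to-pay. Maximising NMB at a threshold is
#' equivalent to the ICER decision rule.
#'
#' @param cost Cost (GBP); vectorised.
#' @param effect Effect (QALYs or probability of successful treatment).
#' @param wtp Willingness-to-pay per unit effect (GBP).
#' @return Net monetary benefit (GBP).
#' @export
nmb <- function(cost, effect, wtp) {
  wtp * effect - cost
}

#' Incremental cost-effectiveness frontier with dominance handling
#'
#' Sorts strategies by expected cost, removes strictly dominated strategies
#' (at least as costly and no more effective than another, one strictly),
#' then extended-dominated strategies (those whose removal restores a
#' strictly increasing ICER sequence along the frontier), and reports the
#' ICER of each frontier member against the previous (next-cheapest)
#' frontier member. Exact cost-and-effect ties are resolved
#' deterministically: the strategy earlier in identifier order stays on the
#' frontier, the other is flagged dominated.
#'
#' @param outcomes Data frame with columns `strategy`, `cost`, and the
#'   effect column named by `effect` (>= 2 rows, unique strategies), e.g.
#'   from [evaluate_strategies()].
#' @param effect Name of the effect column: `"qalys"` or `"p_success"`.
#' @return A `frontier_table` data frame: `strategy`, `cost`, `effect`,
#'   `status` (`on_frontier`, `dominated`, `extended_dominated`), `icer`
#'   (GBP per unit effect vs the previous frontier member; `NA` for the
#'   cheapest), sorted by cost.
#' @examples
#' out <- data.frame(strategy = c("A", "B", "C"),
#'                   cost = c(100, 200, 150), qalys = c(1, 0.5, 1.2))
#' frontier(out, "qalys")
#' @export
frontier <- function(outcomes, effect = c("qalys", "p_success")) {
  effect <- if (is.character(effect) && effect[1] %in% names(outcomes))
    effect[1] else match.arg(effect)
  stopifnot(is.data.frame(outcomes), nrow(outcomes) >= 2,
            all(c("strategy", "cost", effect) %in% names(outcomes)))
  if (anyDuplicated(outcomes$strategy))
    stop("duplicate strategy ids in `outcomes`")

  df <- data.frame(strategy = as.character(outcomes$strategy),
                   cost = outcomes$cost,
                   effect = outcomes[[effect]],
                   stringsAsFactors = FALSE)
  df <- df[order(df$cost, -df$effect, df$strategy), ]
  n <- nrow(df)
  status <- rep("on_frontier", n)

  # strict dominance (pairwise); ties resolved by sort order above
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      ci <- df$cost[i]; cj <- df$cost[j]
      ei <- df$effect[i]; ej <- df$effect[j]
      if (cj < ci && ej >= ei || cj <= ci && ej > ei) {
        status[i] <- "dominated"
        break
      }
      if (ci == cj && ei == ej && j < i) {  # exact tie: earlier row wins
        status[i] <- "dominated"
        break
      }
    }
  }

  # extended dominance: enforce strictly increasing ICERs along the frontier
  repeat {
    idx <- which(status == "on_frontier")
    if (length(idx) < 3) break
    ic <- diff(df$cost[idx]) / diff(df$effect[idx])
    bad <- which(diff(ic) <= 0)
    if (!length(bad)) break
    status[idx[bad[1] + 1L]] <- "extended_dominated"
  }

  icer <- rep(NA_real_, n)
  idx <- which(status == "on_frontier")
  if (length(idx) > 1)
    icer[idx[-1]] <- diff(df$cost[idx]) / diff(df$effect[idx])

  df$status <- status
  df$icer <- icer
  rownames(df) <- NULL
  class(df) <- c("frontier_table", "data.frame")
  attr(df, "effect") <- effect
  df
}

#' @export
print.frontier_table <- function(x, digits = 3, ...) {
  cat("Cost-effectiveness frontier (effect:", attr(x, "effect"), ")\n")
  y <- x
  y$cost <- round(y$cost)
  y$icer <- round(y$icer / 100) * 100  # presentation to the nearest 100
  print.data.frame(y, digits = digits, ...)
  invisible(x)
}
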