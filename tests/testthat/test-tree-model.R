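ps <- load_parameters()
pp <- point_estimates(ps)

test_that("path probabilities conserve to one on every strategy and scenario", {
  for (s in strategy_ids()) {
    tr <- build_strategy_tree(s, pp)
    p <- enumerate_paths(tr, pp)
    expect_lt(abs(sum(p$probability) - 1), 1e-9)
    expect_true(all(p$probability >= 0))
  }
  for (sc in c("single_test_only", "uds_accuracy_low_plus_diary", "expert_high")) {
    sps <- apply_scenario(ps, sc)
    spp <- point_estimates(sps)
    for (s in strategy_ids()) {
      p <- enumerate_paths(build_strategy_tree(s, sps), spp)
      expect_lt(abs(sum(p$probability) - 1), 1e-9)
    }
  }
})

test_that("rollback equals path-enumeration aggregation on every tree", {
  for (s in strategy_ids()) {
    tr <- build_strategy_tree(s, pp)
    v <- evaluate(tr, pp)
    p <- enumerate_paths(tr, pp)
    expect_equal(v$cost, sum(p$probability * p$discounted_cost),
                 tolerance = 1e-9)
    expect_equal(v$qalys, sum(p$probability * p$discounted_qalys),
                 tolerance = 1e-9)
    expect_equal(v$p_success, sum(p$probability[p$cured]), tolerance = 1e-9)
  }
})

test_that("a hand-built three-leaf tree matches its arithmetic expectation", {
  leaf <- function(cond, cure_year = NA_integer_, se = FALSE)
    oabcea:::terminal_node(list(d = cond, se = se), cure_year)
  tree <- oabcea:::chance_node("toy", list(
    oabcea:::branch_of("a", oabcea:::f_const(0.5), leaf("do", 1L),
                       costs = list(list(ref = "cost_sling", coef = 1))),
    oabcea:::branch_of("b", oabcea:::f_const(0.3), leaf("do", 2L, se = TRUE)),
    oabcea:::branch_of("c", oabcea:::f_const(0.2), leaf("do"))))
  attr(tree, "econ") <- list(horizon = 5L, rate = 0.035)
  attr(tree, "strategy") <- "toy"
  class(tree) <- c("strategy_tree", "list")
  v <- evaluate(tree, pp)
  D <- discount_factor(1:5, 0.035)
  u <- pp$values
  q_a <- u[["util_cured"]] * sum(D)
  q_b <- u[["util_do"]] * D[1] + u[["util_cured_se"]] * sum(D[2:5])
  q_c <- u[["util_do"]] * sum(D)
  expect_equal(v$cost, 0.5 * u[["cost_sling"]], tolerance = 1e-12)
  expect_equal(v$qalys, 0.5 * q_a + 0.3 * q_b + 0.2 * q_c, tolerance = 1e-12)
  expect_equal(v$p_success, 0.8, tolerance = 1e-12)
})

test_that("QALY accrual follows the discounting convention", {
  econ0 <- list(horizon_years = 5, discount_rate = 0)
  econ35 <- list(horizon_years = 5, discount_rate = 0.035)
  tl <- function(state) data.frame(state = state, start_year = 1, end_year = 5)
  expect_equal(accrue_qalys(tl("well"), c(well = 1), econ0), 5)
  expect_equal(accrue_qalys(tl("well"), c(well = 1), econ35),
               1 + sum(1 / 1.035^(1:4)), tolerance = 1e-12)
  # cured at entry with botulinum-induced side effects
  expect_equal(accrue_qalys(tl("cured_se"), c(cured_se = 0.87), econ0), 4.35)
  # split timeline: symptomatic two years, cured from year 3
  split <- data.frame(state = c("do", "cured"), start_year = c(1, 3),
                      end_year = c(2, 5))
  expect_equal(accrue_qalys(split, c(do = 0.6, cured = 0.92), econ0),
               2 * 0.6 + 3 * 0.92)
  bad <- data.frame(state = c("do", "cured"), start_year = c(1, 2),
                    end_year = c(2, 5))
  expect_error(accrue_qalys(bad, c(do = 0.6, cured = 0.92), econ0),
               "overlap")
})

test_that("with certain cure the expected cost is test plus first-line treatment", {
  v <- pp$values
  v[grep("^cure_", names(v))] <- 1
  v[["p_voiding_difficulty"]] <- 0
  v[["acc_uds_do_sens"]] <- 1
  tr <- build_strategy_tree("uds_all", pp)
  out <- evaluate(tr, v)
  D <- discount_factor(1:5, 0.035)
  w <- c(1, 0.8, 0.736)
  botox_course <- v[["cost_botulinum_injection"]] * sum(w * D[1:3])
  # responders to neurostimulation still accrue monthly maintenance sessions
  neuro <- v[["cost_neurostim_course"]] *
    (1 + (9 / 12) * D[1] + sum(D[2:5]))
  p_b <- v[["p_choose_botox_over_neurostim"]]
  first_cost <- c(
    do = p_b * botox_course + (1 - p_b) * neuro,
    stress = v[["cost_sling"]],
    mixed = v[["p_choose_botox_prior_sling"]] * botox_course +
      (1 - v[["p_choose_botox_prior_sling"]]) * v[["cost_sling"]],
    normal = 0, low_compliance = 0, voiding_dysfunction = 0)
  prev <- v[paste0("prev_", names(first_cost))]
  expect_equal(out$cost,
               v[["cost_urodynamics"]] + sum(prev * first_cost),
               tolerance = 1e-9)
  expect_equal(out$p_success, sum(prev[1:3]), tolerance = 1e-9)
})

test_that("a detrusor-overactivity diagnosis offers exactly two first-line modalities", {
  tr <- build_strategy_tree("uds_all", pp)
  p <- enumerate_paths(tr, pp)
  do_traces <- p$trace[startsWith(p$trace, "do >") &
                         grepl("do_detected", p$trace)]
  first_treatment <- vapply(strsplit(do_traces, " > "), function(tok) {
    tok[grep("^botulinum$|^neurostimulation$|^sling_first$", tok)[1]]
  }, character(1))
  expect_setequal(unique(first_treatment), c("botulinum", "neurostimulation"))
})

test_that("outcomes are monotone in cure probabilities and unit costs", {
  base <- evaluate(build_strategy_tree("history_all", pp), pp)
  for (nm in c("cure_botulinum_do", "cure_sling_mixed", "cure_colpo_stress",
               "cure_implant_do")) {
    v <- pp$values
    v[[nm]] <- min(v[[nm]] + 0.1, 0.99)
    out <- evaluate(build_strategy_tree("history_all", pp), v)
    expect_gte(out$p_success, base$p_success)
    expect_gte(out$qalys, base$qalys)
  }
  for (nm in c("cost_sling", "cost_botulinum_injection", "cost_implant",
               "cost_urodynamics")) {
    v <- pp$values
    v[[nm]] <- v[[nm]] * 1.5
    for (s in c("uds_all", "history_all")) {
      out <- evaluate(build_strategy_tree(s, pp), v)
      ref <- evaluate(build_strategy_tree(s, pp), pp)
      expect_gte(out$cost, ref$cost)
    }
  }
})

test_that("no pathway leaves a cured state (improvements persist)", {
  for (s in strategy_ids()) {
    p <- enumerate_paths(build_strategy_tree(s, pp), pp)
    cured_pos <- regexpr("cured_y[0-9]", p$trace)
    # a cure label only ever terminates a trace
    hit <- cured_pos > 0
    expect_true(all(substring(p$trace[hit], cured_pos[hit]) ==
                      vapply(strsplit(p$trace[hit], " > "), utils::tail,
                             character(1), 1)))
    expect_identical(hit, p$cured)
  }
})

test_that("ultrasonography for all is dominated under the default inputs", {
  out <- evaluate_strategies(pp, c("uds_all", "ultrasound_all"))
  expect_gt(out$cost[out$strategy == "ultrasound_all"],
            out$cost[out$strategy == "uds_all"])
  expect_lte(out$qalys[out$strategy == "ultrasound_all"],
             out$qalys[out$strategy == "uds_all"])
})

test_that("tree exports render every node", {
  tr <- build_strategy_tree("uds_if_mixed_history", pp)
  txt <- format_tree(tr)
  expect_true(any(grepl("urodynamics", txt)))
  expect_true(any(grepl("cured", txt)))
  dot <- tree_to_dot(tr)
  expect_match(dot, "^digraph")
  expect_match(dot, "bwt_result|clinical_history")
})
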