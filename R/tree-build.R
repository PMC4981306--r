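# Strategy decision trees.
#
# A tree is a nested list of chance nodes and terminals. Branch
# probabilities are symbolic references into the flat parameter vector so
# that one structure serves the base case, every deterministic scenario,
# and all PSA iterations. A branch probability is a product of affine
# factors a + sum(b_i * theta[ref_i]); cost events are attached to
# branches as (parameter reference, coefficient) pairs with discounting
# already folded into the coefficient.

f_const <- function(x) list(a = x, b = numeric(0), ref = character(0))
f_p <- function(ref, w = 1) list(a = 0, b = w, ref = ref)
f_1mp <- function(ref, w = 1) list(a = 1, b = -w, ref = ref)
f_rem <- function(refs, ws) list(a = 1, b = -ws, ref = refs)

chance_node <- function(label, branches) {
  list(kind = "chance", label = label, branches = branches)
}

branch_of <- function(label, prob, child, costs = list()) {
  if (!is.null(prob$a)) prob <- list(prob)  # single factor shorthand
  list(label = label, prob = prob, costs = costs, child = child)
}

# single-branch pass-through node used to attach unconditional costs
node1 <- function(label, costs, child) {
  chance_node(label, list(branch_of(label, f_const(1), child, costs)))
}

terminal_node <- function(st, cure_year = NA_integer_) {
  list(kind = "terminal",
       label = if (is.na(cure_year)) "symptomatic" else paste0("cured_y", cure_year),
       condition = st$d, cure_year = cure_year, side_effects = isTRUE(st$se))
}

# flat-parameter reference for P(subjective cure | treatment, true condition);
# conditions a treatment cannot address use the most conservative
# misdiagnosis proxy (the botulinum-stress entry)
cure_ref <- function(treatment, condition) {
  proxy <- "cure_botulinum_stress"
  tc <- switch(treatment,
    botulinum = c(do = "cure_botulinum_do", stress = "cure_botulinum_stress",
                  mixed = "cure_botulinum_mixed"),
    neurostim = c(do = "cure_neurostim_do",
                  stress = "cure_neurostim_stress_mixed",
                  mixed = "cure_neurostim_stress_mixed"),
    implant = c(do = "cure_implant_do",
                stress = "cure_implant_stress_mixed",
                mixed = "cure_implant_stress_mixed"),
    sling = c(do = "cure_sling_do", stress = "cure_sling_stress",
              mixed = "cure_sling_mixed"),
    colpo = c(do = "cure_colpo_do", stress = "cure_colpo_stress",
              mixed = "cure_colpo_mixed"),
    stop("unknown treatment: ", treatment))
  if (condition %in% names(tc)) tc[[condition]] else proxy
}

util_ref <- function(condition) {
  switch(condition,
    do = "util_do", stress = "util_stress", mixed = "util_mixed",
    normal = "util_normal",
    low_compliance = , voiding_dysfunction = "util_lcvd",
    stop("unknown condition: ", condition))
}

# management category implied by a urodynamic diagnosis
assigned_from_d <- function(d) {
  switch(d, do = "oab", stress = "stress", mixed = "mixed", d)
}

extract_econ <- function(x) {
  econ <- if (inherits(x, "parameter_set") || inherits(x, "point_parameters"))
    x$econ else x
  list(horizon = as.integer(econ$horizon_years %||% 5L),
       rate = econ$discount_rate %||% 0.035,
       dropout = econ$botulinum_dropout %||% c(0.20, 0.08),
       split = econ$botulinum_cure_split %||% c(0.34, 0.52, 0.14),
       second_test = isTRUE(econ$second_test %||% TRUE),
       psa_iterations = econ$psa_iterations %||% 10000L,
       incidence_per_year = econ$incidence_per_year %||% 54000,
       research_horizon_years = econ$research_horizon_years %||% 10L,
       wtp_grid_success = econ$wtp_grid_success,
       wtp_grid_qaly = econ$wtp_grid_qaly)
}

#' Build the decision tree of one test-treat strategy
#'
#' The tree starts from a chance node over the true urodynamic diagnosis,
#' then the clinical-history label, then the strategy's diagnostic work-up,
#' and finally the treatment pathway of the assigned management category:
#' overactive bladder (botulinum toxin or percutaneous neurostimulation,
#' failures to peripheral nerve evaluation then neurostimulator
#' implantation or the alternative modality), stress incontinence (sling,
#' then colposuspension unless overactive-bladder treatment was previously
#' given), mixed incontinence (optional botulinum toxin, then sling, then
#' colposuspension under the same restriction). Women with a urodynamic
#' finding of normal bladder, low compliance only, or voiding dysfunction
#' only receive no further invasive treatment. At most two diagnostic
#' tests are carried out: one at entry (where the strategy tests) and one
#' on failure of the first treatment.
#'
#' @param strategy One of [strategy_ids()].
#' @param params A `parameter_set`, `point_parameters`, or economic-settings
#'   list; only the economic settings (horizon, discount rate, botulinum
#'   course weights, second-test switch) shape the tree.
#' @return A `strategy_tree` (nested list of chance and terminal nodes)
#'   whose branch probabilities reference flat parameter names.
#' @seealso [evaluate()], [enumerate_paths()], [format_tree()]
#' @export
build_strategy_tree <- function(strategy, params = NULL) {
  if (!strategy %in% STRATEGIES)
    stop("unknown strategy '", strategy, "'; valid ids: ",
         paste(STRATEGIES, collapse = ", "))
  econ <- extract_econ(params %||%
                         list(horizon_years = 5, discount_rate = 0.035))
  H <- econ$horizon
  df_y <- function(y) discount_factor(y, econ$rate)
  ci <- function(ref, year, mult = 1) {
    if (year > H) return(NULL)
    list(ref = paste0("cost_", ref), coef = mult * df_y(year))
  }
  costs_of <- function(...) Filter(Negate(is.null), list(...))
  test_cost_item <- function(test, year) {
    switch(test,
      uds = costs_of(ci("urodynamics", year)),
      us = costs_of(ci("ultrasonography", year)),
      history = list())
  }

  leaf_sympt <- function(st) terminal_node(st)
  leaf_cured <- function(st, y) terminal_node(st, cure_year = as.integer(y))
  oab_treated <- function(st)
    any(c("botulinum", "neurostim", "implant") %in% st$treatments)

  # -- treatment stages ----------------------------------------------------

  botox_course <- function(st, on_fail) {
    y <- st$year
    if (y > H) return(leaf_sympt(st))
    n <- min(3L, H - y + 1L)
    w <- botulinum_injection_weights(econ$dropout[1], econ$dropout[2])[1:n]
    s <- econ$split[1:n]
    course_cost <- list(list(ref = "cost_botulinum_injection",
                             coef = sum(w * df_y(y + seq_len(n) - 1L))))
    st <- within_st(st, treatments = c(st$treatments, "botulinum"))
    theta <- cure_ref("botulinum", st$d)
    cure_node <- function(stx) {
      br <- lapply(seq_len(n), function(j)
        branch_of(paste0("cured_inj", j), f_p(theta, s[j]),
                  leaf_cured(stx, y + j - 1L)))
      br <- c(br, list(branch_of("not_cured", f_rem(theta, sum(s)),
                                 on_fail(within_st(stx, year = y + n)))))
      chance_node("botulinum_response", br)
    }
    vd <- chance_node("voiding_dysfunction_risk", list(
      branch_of("voiding_dysfunction", f_p("p_voiding_difficulty"),
                cure_node(within_st(st, se = TRUE)),
                costs = costs_of(ci("selfcath_training", y))),
      branch_of("no_voiding_dysfunction", f_1mp("p_voiding_difficulty"),
                cure_node(st))))
    node1("botulinum_course", course_cost, vd)
  }

  neurostim_course <- function(st, on_fail) {
    y <- st$year
    if (y > H) return(leaf_sympt(st))
    st <- within_st(st, treatments = c(st$treatments, "neurostim"))
    theta <- cure_ref("neurostim", st$d)
    # responders need a monthly maintenance session (months 4..end of
    # horizon), costed at one twelfth of the 12-session course
    maint <- lapply(y:H, function(yy)
      ci("neurostim_course", yy, mult = (if (yy == y) 9 else 12) / 12))
    resp <- chance_node("neurostim_response", list(
      branch_of("cured", f_p(theta), leaf_cured(st, y),
                costs = Filter(Negate(is.null), maint)),
      branch_of("not_cured", f_1mp(theta),
                on_fail(within_st(st, year = y + 1L)))))
    node1("neurostim_course", costs_of(ci("neurostim_course", y)), resp)
  }

  sling_stage <- function(st, on_fail) {
    y <- st$year
    if (y > H || "sling" %in% st$treatments) return(on_fail(st))
    st2 <- within_st(st, treatments = c(st$treatments, "sling"))
    theta <- cure_ref("sling", st$d)
    node1("sling_surgery", costs_of(ci("sling", y)),
          chance_node("sling_response", list(
            branch_of("cured", f_p(theta), leaf_cured(st2, y)),
            branch_of("not_cured", f_1mp(theta),
                      on_fail(within_st(st2, year = y + 1L))))))
  }

  colpo_stage <- function(st, on_fail) {
    y <- st$year
    if (y > H || "colpo" %in% st$treatments) return(on_fail(st))
    st2 <- within_st(st, treatments = c(st$treatments, "colpo"))
    theta <- cure_ref("colpo", st$d)
    node1("colposuspension", costs_of(ci("colposuspension", y)),
          chance_node("colposuspension_response", list(
            branch_of("cured", f_p(theta), leaf_cured(st2, y)),
            branch_of("not_cured", f_1mp(theta),
                      on_fail(within_st(st2, year = y + 1L))))))
  }

  followup_node <- function(leaf) {
    # neurostimulator follow-up events, costed at the end of the horizon
    refs <- c("p_revision_lt2y", "p_revision_ge2y", "p_maintenance_ge2y",
              "p_removal")
    ev <- lapply(refs, function(r)
      branch_of(sub("^p_", "", r), f_p(r), leaf,
                costs = costs_of(ci("implant_followup", H))))
    none <- branch_of("no_followup_event", f_rem(refs, rep(1, 4)), leaf)
    chance_node("implant_followup", c(ev, list(none)))
  }

  pne_stage <- function(st) {
    y <- st$year
    if (y > H) return(leaf_sympt(st))
    theta <- cure_ref("implant", st$d)
    st_imp <- within_st(st, treatments = c(st$treatments, "implant"))
    implant <- node1("implantation", costs_of(ci("implant", y)),
      chance_node("implant_response", list(
        branch_of("cured", f_p(theta), followup_node(leaf_cured(st_imp, y))),
        branch_of("not_cured", f_1mp(theta),
                  followup_node(leaf_sympt(st_imp))))))
    alt <-
      if (!"botulinum" %in% st$treatments) botox_course(st, leaf_sympt)
      else if (!"neurostim" %in% st$treatments) neurostim_course(st, leaf_sympt)
      else leaf_sympt(st)
    node1("pne", costs_of(ci("pne", y)),
          chance_node("pne_outcome", list(
            branch_of("implantation", f_p("p_require_implant"), implant),
            branch_of("alternative_modality", f_1mp("p_require_implant"), alt))))
  }

  # -- second diagnostic test ---------------------------------------------

  second_test <- function(st, assigned, resume) {
    if (!econ$second_test || st$test_used)
      return(resume(within_st(st, test_used = TRUE), assigned))
    st <- within_st(st, test_used = TRUE)
    y <- st$year
    if (y > H) return(resume(st, assigned))
    if (st$tested_at_entry || st$test == "history") {
      # confirmatory repeat of the entry work-up: cost only (history is
      # free and uninformative on repeat)
      child <- resume(st, assigned)
      cost <- test_cost_item(if (st$tested_at_entry) st$test else "history", y)
      return(if (length(cost)) node1("repeat_test", cost, child) else child)
    }
    if (st$test == "uds") {
      child <-
        if (st$d == "do") {
          chance_node("second_uds_result", list(
            branch_of("do_detected", f_p("acc_uds_do_sens"),
                      resume(st, "oab")),
            branch_of("do_missed", f_1mp("acc_uds_do_sens"),
                      resume(st, "mixed"))))
        } else {
          resume(st, assigned_from_d(st$d))
        }
      node1("second_test_uds", test_cost_item("uds", y), child)
    } else {  # ultrasound
      pos <- if (st$d == "do") f_p("acc_bwt_sens") else f_1mp("acc_bwt_spec")
      neg <- if (st$d == "do") f_1mp("acc_bwt_sens") else f_p("acc_bwt_spec")
      node1("second_test_us", test_cost_item("us", y),
            chance_node("second_us_result", list(
              branch_of("bwt_high", pos, resume(st, "oab")),
              branch_of("bwt_low", neg, resume(st, "mixed")))))
    }
  }

  # -- management pathways -------------------------------------------------

  oab_resume <- function(st, assigned) {
    switch(assigned,
      oab = pne_stage(st),
      stress = stress_continue(st),
      mixed = mixed_continue(st),
      leaf_sympt(st))
  }

  oab_first_fail <- function(st) second_test(st, "oab", oab_resume)

  oab_entry <- function(st) {
    botox_ok <- !"botulinum" %in% st$treatments
    neuro_ok <- !"neurostim" %in% st$treatments
    if (botox_ok && neuro_ok) {
      chance_node("oab_modality_choice", list(
        branch_of("botulinum", f_p("p_choose_botox_over_neurostim"),
                  botox_course(st, oab_first_fail)),
        branch_of("neurostimulation", f_1mp("p_choose_botox_over_neurostim"),
                  neurostim_course(st, oab_first_fail))))
    } else if (botox_ok) {
      botox_course(st, oab_first_fail)
    } else if (neuro_ok) {
      neurostim_course(st, oab_first_fail)
    } else {
      pne_stage(st)
    }
  }

  stress_continue <- function(st) {
    if (!"sling" %in% st$treatments) sling_stage(st, maybe_colpo)
    else maybe_colpo(st)
  }

  maybe_colpo <- function(st) {
    if (!oab_treated(st)) colpo_stage(st, leaf_sympt) else leaf_sympt(st)
  }

  stress_resume <- function(st, assigned) {
    switch(assigned,
      stress = stress_continue(st),
      oab = oab_entry(st),
      mixed = mixed_continue(st),
      leaf_sympt(st))
  }

  stress_entry <- function(st) {
    sling_stage(st, function(s) second_test(s, "stress", stress_resume))
  }

  mixed_continue <- function(st) {
    if (!"sling" %in% st$treatments) sling_stage(st, maybe_colpo)
    else maybe_colpo(st)
  }

  mixed_resume <- function(st, assigned) {
    switch(assigned,
      mixed = mixed_continue(st),
      stress = stress_continue(st),
      oab = if (oab_treated(st)) pne_stage(st) else oab_entry(st),
      leaf_sympt(st))
  }

  mixed_entry <- function(st) {
    fail <- function(s) second_test(s, "mixed", mixed_resume)
    if (!oab_treated(st) && !"botulinum" %in% st$treatments) {
      chance_node("mixed_botox_option", list(
        branch_of("botulinum_first", f_p("p_choose_botox_prior_sling"),
                  botox_course(st, fail)),
        branch_of("sling_first", f_1mp("p_choose_botox_prior_sling"),
                  sling_stage(st, fail))))
    } else {
      sling_stage(st, fail)
    }
  }

  pathway <- function(assigned, st) {
    switch(assigned,
      oab = oab_entry(st),
      stress = stress_entry(st),
      mixed = mixed_entry(st),
      leaf_sympt(st))
  }

  # -- entry work-up per strategy ------------------------------------------

  uds_assign <- function(st) {
    if (st$d == "do") {
      chance_node("uds_result", list(
        branch_of("do_detected", f_p("acc_uds_do_sens"), pathway("oab", st)),
        branch_of("do_missed", f_1mp("acc_uds_do_sens"), pathway("mixed", st))))
    } else {
      pathway(assigned_from_d(st$d), st)
    }
  }

  us_assign <- function(st) {
    pos <- if (st$d == "do") f_p("acc_bwt_sens") else f_1mp("acc_bwt_spec")
    neg <- if (st$d == "do") f_1mp("acc_bwt_sens") else f_p("acc_bwt_spec")
    chance_node("bwt_result", list(
      branch_of("bwt_high", pos, pathway("oab", st)),
      branch_of("bwt_low", neg, pathway("mixed", st))))
  }

  entry <- function(d, h) {
    st0 <- function(test, tested) {
      list(d = d, year = 1L, treatments = character(0), test = test,
           tested_at_entry = tested, test_used = FALSE, se = FALSE)
    }
    by_history <- function(test) {
      st <- st0(test, tested = FALSE)
      pathway(if (h == "mixed") "mixed" else "oab", st)
    }
    with_uds <- function() {
      st <- st0("uds", tested = TRUE)
      node1("urodynamics", test_cost_item("uds", 1L), uds_assign(st))
    }
    with_us <- function() {
      st <- st0("us", tested = TRUE)
      node1("ultrasonography", test_cost_item("us", 1L), us_assign(st))
    }
    switch(strategy,
      uds_all = with_uds(),
      ultrasound_all = with_us(),
      history_all = by_history("history"),
      uds_if_mixed_history = if (h == "mixed") with_uds() else by_history("uds"),
      uds_if_oab_history = if (h == "urgency_only") with_uds() else by_history("uds"),
      ultrasound_if_mixed_history = if (h == "mixed") with_us() else by_history("us"),
      ultrasound_if_oab_history = if (h == "urgency_only") with_us() else by_history("us"))
  }

  diag_branches <- lapply(CONDITIONS, function(d) {
    hist_ref <- paste0("hist_mixed_", d)
    hnode <- chance_node("clinical_history", list(
      branch_of("mixed_history", f_p(hist_ref), entry(d, "mixed")),
      branch_of("urgency_only_history", f_1mp(hist_ref),
                entry(d, "urgency_only"))))
    branch_of(d, f_p(paste0("prev_", d)), hnode)
  })
  tree <- chance_node(paste0("strategy_", strategy), diag_branches)
  structure(tree, class = c("strategy_tree", "list"),
            strategy = strategy, econ = econ)
}

# shallow state update helper
within_st <- function(st, ...) {
  upd <- list(...)
  st[names(upd)] <- upd
  st
}

#' Render a strategy tree as an indented outline
#'
#' One line per node/branch, for visual audit of the pathway wiring.
#'
#' @param tree A `strategy_tree`.
#' @param max_depth Truncate below this depth.
#' @return Character vector of lines (invisibly printed by `cat`-ing).
#' @export
format_tree <- function(tree, max_depth = Inf) {
  out <- character(0)
  fmt_prob <- function(prob) {
    paste(vapply(prob, function(f) {
      if (!length(f$ref)) return(sprintf("%g", f$a))
      terms <- paste(sprintf("%+g*%s", f$b, f$ref), collapse = "")
      if (f$a != 0) paste0("(", f$a, terms, ")") else sub("^\\+", "", terms)
    }, character(1)), collapse = " * ")
  }
  walk <- function(node, depth, prefix) {
    if (depth > max_depth) return()
    pad <- strrep("  ", depth)
    if (node$kind == "terminal") {
      out[[length(out) + 1L]] <<- paste0(pad, prefix, "[", node$label,
        " | true: ", node$condition,
        if (node$side_effects) " | side-effects" else "", "]")
      return()
    }
    out[[length(out) + 1L]] <<- paste0(pad, prefix, node$label)
    for (b in node$branches) {
      cst <- if (length(b$costs))
        paste0(" {", paste(vapply(b$costs, function(cc)
          sprintf("%s x %.3f", cc$ref, cc$coef), character(1)),
          collapse = ", "), "}") else ""
      walk(b$child, depth + 1L, paste0("- ", b$label, " p=",
                                       fmt_prob(b$prob), cst, " -> "))
    }
  }
  walk(tree, 0L, "")
  unlist(out)
}

#' Export a strategy tree in DOT (Graphviz) format
#'
#' @param tree A `strategy_tree`.
#' @param file Optional path; when given the DOT text is written there.
#' @return The DOT source as a character scalar (invisibly when `file` is
#'   given).
#' @export
tree_to_dot <- function(tree, file = NULL) {
  lines <- c("digraph strategy_tree {", "  node [shape=box, fontsize=10];")
  counter <- new.env()
  counter$i <- 0L
  nid <- function() {
    counter$i <- counter$i + 1L
    paste0("n", counter$i)
  }
  walk <- function(node) {
    id <- nid()
    shape <- if (node$kind == "terminal") "oval" else "box"
    lines[[length(lines) + 1L]] <<- sprintf('  %s [label="%s", shape=%s];',
                                            id, node$label, shape)
    if (node$kind == "chance") {
      for (b in node$branches) {
        cid <- walk(b$child)
        lines[[length(lines) + 1L]] <<- sprintf('  %s -> %s [label="%s"];',
                                                id, cid, b$label)
      }
    }
    id
  }
  walk(tree)
  lines[[length(lines) + 1L]] <- "}"
  txt <- paste(unlist(lines), collapse = "\n")
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' @export
print.strategy_tree <- function(x, max_depth = 3, ...) {
  cat(format_tree(x, max_depth = max_depth), sep = "\n")
  cat("... (print limited to depth", max_depth, ")\n")
  invisible(x)
}
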