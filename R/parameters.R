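#' @importFrom stats setNames
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Canonical category / key vocabularies used across the package.
CONDITIONS <- c("do", "stress", "mixed", "normal", "low_compliance",
                "voiding_dysfunction")
TREATMENTS <- c("botulinum", "neurostim", "implant", "sling", "colpo")
STRATEGIES <- c("uds_all", "history_all", "ultrasound_all",
                "uds_if_mixed_history", "uds_if_oab_history",
                "ultrasound_if_mixed_history", "ultrasound_if_oab_history")
SCENARIOS <- c("uds_cost_low", "sling_cost_double", "cure_utility_low",
               "uds_accuracy_low_plus_diary", "expert_low", "expert_high",
               "single_test_only")

#' Strategy and scenario identifiers
#'
#' `strategy_ids()` lists the seven test-treat strategies: urodynamics,
#' clinical history, or bladder ultrasonography for all women, and each
#' test restricted to women whose clinical history is mixed incontinence or
#' overactive bladder (with the other arm managed on history alone).
#' `scenario_ids()` lists the deterministic sensitivity-analysis scenarios.
#'
#' @return Character vector of identifiers.
#' @export
strategy_ids <- function() STRATEGIES

#' @rdname strategy_ids
#' @export
scenario_ids <- function() SCENARIOS

parse_dist_entry <- function(entry, key) {
  if (inherits(entry, "fitted_dist")) return(entry)
  if (!is.list(entry))
    stop("parameter '", key, "' must be a distribution specification list")
  d <-
    if (!is.null(entry$beta)) {
      dist_beta(entry$beta[[1]], entry$beta[[2]])
    } else if (!is.null(entry$gamma)) {
      dist_gamma(entry$gamma[[1]], entry$gamma[[2]])
    } else if (!is.null(entry$dirichlet)) {
      conc <- unlist(entry$dirichlet)
      dist_dirichlet(conc)
    } else if (!is.null(entry$point)) {
      dist_point(unlist(entry$point))
    } else if (!is.null(entry$counts)) {
      fit_beta_from_counts(entry$counts[[1]], entry$counts[[2]])
    } else if (!is.null(entry$mean) && !is.null(entry$ci)) {
      fit <- entry$fit %||% if (entry$mean < 1) "beta" else "gamma"
      ci <- unlist(entry$ci)
      if (fit == "beta") fit_beta_from_mean_ci(entry$mean, ci[1], ci[2])
      else fit_gamma_from_mean_ci(entry$mean, ci[1], ci[2])
    } else {
      stop("parameter '", key, "' has no recognised distribution specification")
    }
  if (!is.null(entry$ci)) attr(d, "ci") <- unlist(entry$ci)
  if (isTRUE(entry$expert)) attr(d, "expert") <- TRUE
  d
}

#' Load the complete model parameter set
#'
#' Builds a `parameter_set` from the packaged default configuration
#' (published cure probabilities, pathway probabilities, unit costs and
#' utilities; synthetic accuracy and prevalence stand-ins), optionally
#' overridden by a user configuration.
#'
#' @param config `NULL` for the packaged defaults, a path to a YAML or JSON
#'   file, or a nested list with the same structure. User values are merged
#'   recursively over the defaults.
#' @return A `parameter_set`: nested lists of [dist_beta()]-style
#'   `fitted_dist` objects under `$cure`, `$pathway`, `$costs`,
#'   `$utilities`, `$accuracy`, `$prevalence`, plus economic settings under
#'   `$econ`.
#' @examples
#' ps <- load_parameters()
#' dist_mean(ps$costs$urodynamics)        # 401 to the nearest pound
#' dist_mean(ps$cure$sling$stress)        # 0.868
#' @export
load_parameters <- function(config = NULL) {
  default_path <- system.file("extdata", "default_config.yaml",
                              package = "oabcea", mustWork = TRUE)
  cfg <- yaml::read_yaml(default_path)
  if (!is.null(config)) {
    user <- if (is.character(config)) {
      if (grepl("\\.json$", config)) jsonlite::read_json(config,
                                                         simplifyVector = FALSE)
      else yaml::read_yaml(config)
    } else if (is.list(config)) {
      config
    } else {
      stop("`config` must be NULL, a file path, or a list")
    }
    cfg <- merge_config(cfg, user)
  }
  build_parameter_set(cfg)
}

# Recursive override merge. A user entry that itself specifies a
# distribution replaces the default entry wholesale (so `{point: 250}`
# supersedes a default `{gamma: [...], ci: [...]}` rather than coexisting
# with it); NULL removes a key; everything else merges per key.
merge_config <- function(default, user) {
  dist_keys <- c("beta", "gamma", "dirichlet", "point", "counts", "mean")
  for (nm in names(user)) {
    uv <- user[[nm]]
    if (is.null(uv)) {
      default[nm] <- NULL
    } else if (is.list(uv) && any(dist_keys %in% names(uv))) {
      default[[nm]] <- uv
    } else if (is.list(uv) && is.list(default[[nm]])) {
      default[[nm]] <- merge_config(default[[nm]], uv)
    } else {
      default[[nm]] <- uv
    }
  }
  default
}

build_parameter_set <- function(cfg) {
  need <- function(x, key) {
    if (is.null(x)) stop("required configuration key missing: ", key)
    x
  }
  parse_section <- function(section, path) {
    out <- list()
    for (nm in names(section)) {
      if (nm %in% c("synthetic", "dirichlet")) next
      entry <- section[[nm]]
      key <- paste(path, nm, sep = ".")
      out[[nm]] <- if (is.list(entry) && is.null(names(entry)) ||
                       (is.list(entry) &&
                        !any(c("beta", "gamma", "dirichlet", "point",
                               "counts", "mean") %in% names(entry)))) {
        parse_section(entry, key)
      } else {
        parse_dist_entry(entry, key)
      }
    }
    out
  }
  cure <- parse_section(need(cfg$cure, "cure"), "cure")
  for (tr in c("botulinum", "neurostim", "implant", "sling", "colpo"))
    need(cure[[tr]], paste0("cure.", tr))
  pathway <- parse_section(need(cfg$pathway, "pathway"), "pathway")
  costs <- parse_section(need(cfg$costs, "costs"), "costs")
  utilities <- parse_section(need(cfg$utilities, "utilities"), "utilities")
  accuracy <- parse_section(need(cfg$accuracy, "accuracy"), "accuracy")
  prevalence <- parse_dist_entry(list(dirichlet = need(cfg$prevalence$dirichlet,
                                                       "prevalence.dirichlet")),
                                 "prevalence")

  for (nm in names(costs)) {
    if (dist_mean(costs[[nm]]) <= 0)
      stop("cost '", nm, "' must have a positive mean")
  }
  probs <- c(unlist(cure, recursive = FALSE), pathway,
             list(bwt_sensitivity = accuracy$bwt_sensitivity,
                  bwt_specificity = accuracy$bwt_specificity))
  for (nm in names(probs)) {
    m <- dist_mean(probs[[nm]])
    if (any(m <= 0 | m >= 1))
      stop("probability '", nm, "' must have mean in (0, 1)")
  }
  for (nm in names(utilities)) {
    m <- dist_mean(utilities[[nm]])
    if (m <= 0 || m > 1) stop("utility '", nm, "' must have mean in (0, 1]")
  }

  econ <- need(cfg$econ, "econ")
  econ$discount_rate <- need(econ$discount_rate, "econ.discount_rate")
  stopifnot(econ$discount_rate >= 0, econ$discount_rate < 1,
            econ$horizon_years >= 1)
  econ$botulinum_dropout <- unlist(econ$botulinum_dropout %||% c(0.20, 0.08))
  econ$botulinum_cure_split <- unlist(econ$botulinum_cure_split %||%
                                        c(0.34, 0.52, 0.14))
  econ$second_test <- econ$second_test %||% TRUE

  structure(list(cure = cure, pathway = pathway, costs = costs,
                 utilities = utilities, accuracy = accuracy,
                 prevalence = prevalence, econ = econ,
                 scenario_settings = cfg$scenario_settings %||% list(),
                 price_base = cfg$price_base %||% "2012-13",
                 synthetic_accuracy = isTRUE(cfg$accuracy$synthetic),
                 scenario = "basecase"),
            class = "parameter_set")
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set> scenario:", x$scenario,
      "| price base:", x$price_base, "\n")
  cat("  cure entries:", length(unlist(x$cure, recursive = FALSE)),
      "| costs:", length(x$costs),
      "| utilities:", length(x$utilities), "\n")
  if (isTRUE(x$synthetic_accuracy))
    cat("  accuracy/prevalence inputs: SYNTHETIC stand-ins\n")
  invisible(x)
}

# Flat parameter vocabulary -------------------------------------------------

flat_param_names <- function() {
  c(paste0("prev_", CONDITIONS),
    paste0("hist_mixed_", CONDITIONS),
    "acc_bwt_sens", "acc_bwt_spec", "acc_uds_do_sens",
    "cure_botulinum_do", "cure_botulinum_mixed", "cure_botulinum_stress",
    "cure_neurostim_do", "cure_neurostim_stress_mixed",
    "cure_implant_do", "cure_implant_stress_mixed",
    "cure_sling_do", "cure_sling_stress", "cure_sling_mixed",
    "cure_colpo_do", "cure_colpo_stress", "cure_colpo_mixed",
    "p_choose_botox_prior_sling", "p_choose_botox_over_neurostim",
    "p_voiding_difficulty", "p_require_implant",
    "p_revision_lt2y", "p_revision_ge2y", "p_maintenance_ge2y", "p_removal",
    paste0("cost_", names_cost_keys()),
    paste0("util_", c("do", "stress", "mixed", "normal", "lcvd",
                      "cured", "cured_se")))
}

names_cost_keys <- function() {
  c("urodynamics", "ultrasonography", "botulinum_injection",
    "neurostim_course", "sling", "pne", "implant", "implant_followup",
    "colposuspension", "selfcath_training")
}

# Map every flat scalar parameter to its fitted_dist (Dirichlet groups are
# returned separately: their components are sampled jointly).
flatten_parameters <- function(ps) {
  dists <- list()
  groups <- list()

  groups$prevalence <- list(dist = ps$prevalence,
                            members = paste0("prev_", CONDITIONS))
  for (d in CONDITIONS) {
    hd <- ps$accuracy$history_mixed_given[[d]]
    if (is.null(hd)) stop("accuracy.history_mixed_given missing category: ", d)
    nm <- paste0("hist_mixed_", d)
    if (hd$kind == "dirichlet") {
      conc <- hd$params$concentrations
      # two-category Dirichlet: the 'mixed' share is Beta(a_mixed, a_other)
      dists[[nm]] <- dist_beta(conc[["mixed"]], sum(conc) - conc[["mixed"]])
    } else {
      dists[[nm]] <- hd
    }
  }
  dists$acc_bwt_sens <- ps$accuracy$bwt_sensitivity
  dists$acc_bwt_spec <- ps$accuracy$bwt_specificity
  dists$acc_uds_do_sens <- ps$accuracy$uds_do_sensitivity %||% dist_point(1)

  cure_map <- list(
    cure_botulinum_do = ps$cure$botulinum$do,
    cure_botulinum_mixed = ps$cure$botulinum$mixed,
    cure_botulinum_stress = ps$cure$botulinum$stress,
    cure_neurostim_do = ps$cure$neurostim$do,
    cure_neurostim_stress_mixed = ps$cure$neurostim$stress_mixed,
    cure_implant_do = ps$cure$implant$do,
    cure_implant_stress_mixed = ps$cure$implant$stress_mixed,
    cure_sling_do = ps$cure$sling$do,
    cure_sling_stress = ps$cure$sling$stress,
    cure_sling_mixed = ps$cure$sling$mixed,
    cure_colpo_do = ps$cure$colpo$do,
    cure_colpo_stress = ps$cure$colpo$stress,
    cure_colpo_mixed = ps$cure$colpo$mixed)
  dists <- c(dists, cure_map)

  pw <- ps$pathway
  dists <- c(dists, list(
    p_choose_botox_prior_sling = pw$choose_botox_prior_sling,
    p_choose_botox_over_neurostim = pw$choose_botox_over_neurostim,
    p_voiding_difficulty = pw$voiding_difficulty,
    p_require_implant = pw$require_implant,
    p_revision_lt2y = pw$revision_lt2y,
    p_revision_ge2y = pw$revision_ge2y,
    p_maintenance_ge2y = pw$maintenance_ge2y,
    p_removal = pw$removal))

  for (k in names_cost_keys()) {
    if (is.null(ps$costs[[k]])) stop("costs missing required key: ", k)
    dists[[paste0("cost_", k)]] <- ps$costs[[k]]
  }
  umap <- c(do = "do", stress = "stress", mixed = "mixed", normal = "normal",
            lcvd = "lcvd", cured = "cured", cured_se = "cured_se")
  for (k in names(umap)) {
    if (is.null(ps$utilities[[umap[[k]]]]))
      stop("utilities missing required key: ", umap[[k]])
    dists[[paste0("util_", k)]] <- ps$utilities[[umap[[k]]]]
  }

  miss <- vapply(dists, is.null, logical(1))
  if (any(miss)) stop("missing parameters: ",
                      paste(names(dists)[miss], collapse = ", "))
  list(dists = dists, groups = groups)
}

#' Collapse every parameter distribution to its analytic mean
#'
#' Returns the deterministic base-case inputs: a named vector of point
#' values (probabilities, costs, utilities, accuracy and prevalence shares)
#' plus the economic settings, as used by the main analysis. Idempotent.
#'
#' @param ps A `parameter_set` from [load_parameters()].
#' @return A `point_parameters` object: list with `$values` (named numeric)
#'   and `$econ`.
#' @examples
#' pp <- point_estimates(load_parameters())
#' pp$values[["p_choose_botox_over_neurostim"]]  # 0.750
#' @export
point_estimates <- function(ps) {
  if (inherits(ps, "point_parameters")) return(ps)
  stopifnot(inherits(ps, "parameter_set"))
  fl <- flatten_parameters(ps)
  vals <- vapply(fl$dists, function(d) as.numeric(dist_mean(d))[1], numeric(1))
  for (g in fl$groups) {
    m <- dist_mean(g$dist)
    vals[g$members] <- as.numeric(m)
  }
  nm <- flat_param_names()
  vals <- vals[nm]
  if (anyNA(vals)) stop("incomplete parameter set: ",
                        paste(nm[is.na(vals)], collapse = ", "))
  structure(list(values = vals, econ = ps$econ, scenario = ps$scenario),
            class = "point_parameters")
}

#' Expected cost of a botulinum toxin course
#'
#' Up to three injections are given at yearly intervals; the proportion of
#' women proceeding to injections 2 and 3 follows the drop-out rates after
#' the first and second injection. The undiscounted expected course cost is
#' `unit_cost * (1 + (1 - d1) + (1 - d1)(1 - d2))`.
#'
#' @param unit_cost Positive cost of one injection (GBP).
#' @param dropout_after_1,dropout_after_2 Drop-out proportions in `[0, 1]`
#'   (defaults 0.20 and 0.08).
#' @return Expected course cost (GBP).
#' @examples
#' expected_botulinum_course_cost(912)  # 912 * 2.536
#' @export
expected_botulinum_course_cost <- function(unit_cost, dropout_after_1 = 0.20,
                                           dropout_after_2 = 0.08) {
  stopifnot(unit_cost > 0, dropout_after_1 >= 0, dropout_after_1 <= 1,
            dropout_after_2 >= 0, dropout_after_2 <= 1)
  unit_cost * sum(botulinum_injection_weights(dropout_after_1, dropout_after_2))
}

# Proportion of women receiving injections 1..3.
botulinum_injection_weights <- function(d1 = 0.20, d2 = 0.08) {
  c(1, 1 - d1, (1 - d1) * (1 - d2))
}

#' Apply a deterministic sensitivity-analysis scenario
#'
#' Returns a modified copy of the parameter set; the input is never
#' mutated. Scenarios: `uds_cost_low` (urodynamics cost to the all-HRG
#' weighted average, GBP 173); `sling_cost_double` (sling cost doubled);
#' `cure_utility_low` (cured utility 0.92 to 0.84);
#' `uds_accuracy_low_plus_diary` (configured alternative accuracy values:
#' imperfect urodynamic DO detection, diary-sharpened history);
#' `expert_low` / `expert_high` (expert-elicited cure probabilities to
#' their interval bounds); `single_test_only` (no second diagnostic test).
#'
#' @param ps A `parameter_set`.
#' @param scenario_id One of [scenario_ids()].
#' @return A modified `parameter_set` with `$scenario` set.
#' @export
apply_scenario <- function(ps, scenario_id) {
  stopifnot(inherits(ps, "parameter_set"))
  if (!scenario_id %in% SCENARIOS)
    stop("unknown scenario '", scenario_id, "'; valid ids: ",
         paste(SCENARIOS, collapse = ", "))
  out <- ps
  st <- ps$scenario_settings[[scenario_id]] %||% list()
  if (scenario_id == "uds_cost_low") {
    out$costs$urodynamics <- dist_point(st$urodynamics_mean %||% 173)
  } else if (scenario_id == "sling_cost_double") {
    f <- st$factor %||% 2
    old <- ps$costs$sling
    out$costs$sling <- if (old$kind == "gamma")
      dist_gamma(old$params$shape, old$params$scale * f)
    else dist_point(dist_mean(old) * f)
  } else if (scenario_id == "cure_utility_low") {
    out$utilities$cured <- dist_point(st$cured_mean %||% 0.84)
  } else if (scenario_id == "uds_accuracy_low_plus_diary") {
    out$accuracy$uds_do_sensitivity <-
      dist_point(st$uds_do_sensitivity %||% 0.92)
    hm <- st$history_mixed_given %||% list()
    for (d in names(hm))
      out$accuracy$history_mixed_given[[d]] <- dist_point(hm[[d]])
  } else if (scenario_id %in% c("expert_low", "expert_high")) {
    pick <- if (scenario_id == "expert_low") 1L else 2L
    for (tr in names(out$cure)) {
      for (cond in names(out$cure[[tr]])) {
        d <- out$cure[[tr]][[cond]]
        if (isTRUE(attr(d, "expert"))) {
          ci <- attr(d, "ci")
          if (is.null(ci)) stop("expert-tagged entry cure.", tr, ".", cond,
                                " has no CI to move to")
          out$cure[[tr]][[cond]] <- dist_point(ci[pick])
        }
      }
    }
  } else if (scenario_id == "single_test_only") {
    out$econ$second_test <- FALSE
  }
  out$scenario <- scenario_id
  out
}
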