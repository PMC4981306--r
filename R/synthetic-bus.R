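# Synthetic cross-sectional cohorts emulating a bladder-ultrasound test
# accuracy study: per woman a true urodynamic diagnosis, a bladder-wall
# thickness (BWT) measurement, a clinical-history label, and a baseline
# utility. The generator supplies the accuracy/prevalence inputs with
# known ground truth, so downstream estimation is testable end to end.

#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate a 209-woman secondary-care cohort of women with
#' refractory overactive bladder or urgency-predominant mixed
#' incontinence: detrusor overactivity (DO) is the most prevalent
#' urodynamic finding and the overall share of mixed-incontinence clinical
#' histories is about 52%. BWT is modelled log-normal within diagnosis
#' (positive, right-skewed); women with DO have thicker bladder walls, so
#' the 5 mm index-test threshold has moderate sensitivity and high-ish
#' specificity. Per-category utilities follow the published Beta
#' distributions.
#'
#' @param n_women Cohort size (default 209).
#' @param diagnosis_mix Named probability vector over the six urodynamic
#'   categories (sums to 1).
#' @param bwt_meanlog,bwt_sdlog Named per-category log-normal parameters
#'   of BWT in mm.
#' @param p_history_mixed Named per-category probability of a
#'   mixed-incontinence (vs urgency-only) clinical history.
#' @param utility_dists Named list of per-category `fitted_dist` utilities.
#' @param seed Integer seed.
#' @return A `bus_generator_config` list.
#' @export
bus_generator_config <- function(n_women = 209L,
                                 diagnosis_mix = NULL,
                                 bwt_meanlog = NULL,
                                 bwt_sdlog = NULL,
                                 p_history_mixed = NULL,
                                 utility_dists = NULL,
                                 seed = 1L) {
  mix <- diagnosis_mix %||% c(do = 0.40, stress = 0.17, mixed = 0.13,
                              normal = 0.20, low_compliance = 0.05,
                              voiding_dysfunction = 0.05)
  ml <- bwt_meanlog %||% c(do = log(4.7), stress = log(4.0), mixed = log(4.2),
                           normal = log(4.0), low_compliance = log(4.0),
                           voiding_dysfunction = log(4.0))
  sl <- bwt_sdlog %||% stats::setNames(rep(0.22, 6), CONDITIONS)
  ph <- p_history_mixed %||% c(do = 0.40, stress = 0.75, mixed = 0.80,
                               normal = 0.40, low_compliance = 0.50,
                               voiding_dysfunction = 0.50)
  ud <- utility_dists %||% list(
    do = dist_beta(8.96, 5.98), stress = dist_beta(18.92, 9.75),
    mixed = dist_beta(49.12, 19.29), normal = dist_beta(22.13, 11.61),
    low_compliance = dist_beta(11.76, 4.05),
    voiding_dysfunction = dist_beta(11.76, 4.05))
  cfg <- list(n_women = as.integer(n_women), diagnosis_mix = mix,
              bwt_meanlog = ml, bwt_sdlog = sl, p_history_mixed = ph,
              utility_dists = ud, seed = as.integer(seed))
  validate_generator_config(cfg)
  structure(cfg, class = "bus_generator_config")
}

validate_generator_config <- function(cfg) {
  if (cfg$n_women < 1L) stop("n_women must be >= 1")
  for (f in c("diagnosis_mix", "bwt_meanlog", "bwt_sdlog", "p_history_mixed"))
    if (!all(CONDITIONS %in% names(cfg[[f]])))
      stop(f, " must be named over all six urodynamic categories")
  if (any(cfg$diagnosis_mix < 0) || abs(sum(cfg$diagnosis_mix) - 1) > 1e-8)
    stop("diagnosis_mix must be a probability vector summing to 1")
  if (any(cfg$bwt_sdlog <= 0)) stop("bwt_sdlog entries must be positive")
  if (any(cfg$p_history_mixed < 0 | cfg$p_history_mixed > 1))
    stop("p_history_mixed entries must be probabilities")
  invisible(cfg)
}

#' Generate a synthetic cross-sectional cohort
#'
#' @param cfg A [bus_generator_config()].
#' @return Data frame with one row per woman: `true_diagnosis` (factor over
#'   the six urodynamic categories), `bwt_mm` (positive), `history_label`
#'   (`"mixed"` / `"urgency_only"`), `baseline_utility` in (0, 1].
#' @examples
#' cohort <- generate_cohort(bus_generator_config(n_women = 50, seed = 7))
#' table(cohort$true_diagnosis)
#' @export
generate_cohort <- function(cfg) {
  validate_generator_config(cfg)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)
  n <- cfg$n_women
  d <- sample(CONDITIONS, n, replace = TRUE,
              prob = cfg$diagnosis_mix[CONDITIONS])
  bwt <- stats::rlnorm(n, meanlog = cfg$bwt_meanlog[d],
                       sdlog = cfg$bwt_sdlog[d])
  hist <- ifelse(stats::runif(n) < cfg$p_history_mixed[d],
                 "mixed", "urgency_only")
  util <- numeric(n)
  for (cond in CONDITIONS) {
    sel <- d == cond
    if (any(sel)) util[sel] <- dist_sample(cfg$utility_dists[[cond]],
                                           sum(sel))
  }
  data.frame(true_diagnosis = factor(d, levels = CONDITIONS),
             bwt_mm = bwt,
             history_label = factor(hist, levels = c("mixed", "urgency_only")),
             baseline_utility = util)
}

#' Write / read a cohort as a delimited file
#'
#' Tab-separated with a header matching the [generate_cohort()] columns.
#'
#' @param cohort A cohort data frame.
#' @param file Path.
#' @return `read_cohort` returns the cohort data frame.
#' @export
write_cohort <- function(cohort, file) {
  utils::write.table(cohort, file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(file)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(file) {
  x <- utils::read.delim(file, stringsAsFactors = FALSE)
  stopifnot(all(c("true_diagnosis", "bwt_mm", "history_label",
                  "baseline_utility") %in% names(x)))
  x$true_diagnosis <- factor(x$true_diagnosis, levels = CONDITIONS)
  x$history_label <- factor(x$history_label,
                            levels = c("mixed", "urgency_only"))
  x
}

wilson_ci <- function(k, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, centre - half), min(1, centre + half))
}

#' Estimate index-test accuracy at a BWT threshold
#'
#' Cross-classifies the BWT index test (positive at or above the
#' threshold) against the urodynamic reference standard (detrusor
#' overactivity; optionally also mixed urodynamic findings) and reports
#' the 2x2 counts plus sensitivity, specificity and predictive values with
#' Wilson 95% confidence intervals.
#'
#' @param cohort A cohort data frame from [generate_cohort()].
#' @param threshold_mm Index-test positivity threshold (default 5 mm).
#' @param reference_includes_mixed Count mixed urodynamic findings as
#'   reference-positive (default `FALSE`).
#' @return An `accuracy_estimate`: list with `tp`, `fp`, `fn`, `tn` and a
#'   data frame `measures` (sensitivity, specificity, ppv, npv with CIs).
#' @export
estimate_accuracy <- function(cohort, threshold_mm = 5,
                              reference_includes_mixed = FALSE) {
  if (!nrow(cohort)) stop("empty cohort")
  pos_ref <- if (reference_includes_mixed) c("do", "mixed") else "do"
  ref <- cohort$true_diagnosis %in% pos_ref
  idx <- cohort$bwt_mm >= threshold_mm
  tp <- sum(idx & ref); fp <- sum(idx & !ref)
  fn <- sum(!idx & ref); tn <- sum(!idx & !ref)
  meas <- function(name, k, n) {
    ci <- wilson_ci(k, n)
    data.frame(measure = name, estimate = if (n > 0) k / n else NA_real_,
               ci_low = ci[1], ci_high = ci[2], n = n)
  }
  measures <- rbind(meas("sensitivity", tp, tp + fn),
                    meas("specificity", tn, tn + fp),
                    meas("ppv", tp, tp + fp),
                    meas("npv", tn, tn + fn))
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 threshold_mm = threshold_mm, measures = measures),
            class = "accuracy_estimate")
}

#' @export
print.accuracy_estimate <- function(x, ...) {
  cat(sprintf("BWT >= %g mm vs urodynamic reference: TP %d FP %d FN %d TN %d\n",
              x$threshold_mm, x$tp, x$fp, x$fn, x$tn))
  print(x$measures, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Estimate the urodynamic diagnosis mix from a cohort
#'
#' Dirichlet concentrations equal to the observed category counts (with an
#' optional +1 smoothing), overall or stratified by clinical-history
#' label.
#'
#' @param cohort A cohort data frame.
#' @param stratify_by_history Return one Dirichlet per history stratum.
#' @param smooth Add 1 to every count (default off).
#' @return A Dirichlet `fitted_dist`, or a named list of two when
#'   stratified.
#' @export
estimate_prevalence <- function(cohort, stratify_by_history = FALSE,
                                smooth = FALSE) {
  if (!nrow(cohort)) stop("empty cohort")
  conc_of <- function(x) {
    counts <- table(factor(x, levels = CONDITIONS))
    conc <- as.numeric(counts) + if (smooth) 1 else 0
    names(conc) <- CONDITIONS
    if (any(conc <= 0))
      stop("zero count for category '",
           CONDITIONS[which(conc <= 0)[1]],
           "'; use `smooth = TRUE` or a larger cohort")
    dist_dirichlet(conc)
  }
  if (!stratify_by_history) return(conc_of(cohort$true_diagnosis))
  strata <- split(cohort$true_diagnosis, cohort$history_label)
  if (any(!lengths(strata)))
    stop("empty history stratum; cannot stratify")
  lapply(strata, conc_of)
}

#' Implied index-test accuracy of a generator configuration
#'
#' Closed-form tail probabilities of the per-category BWT log-normals at
#' the threshold: the oracle against which cohort-based estimates are
#' checked.
#'
#' @inheritParams estimate_accuracy
#' @param cfg A [bus_generator_config()].
#' @return List with `sensitivity` and `specificity` implied by `cfg`.
#' @export
implied_accuracy <- function(cfg, threshold_mm = 5,
                             reference_includes_mixed = FALSE) {
  p_pos <- 1 - stats::plnorm(threshold_mm, cfg$bwt_meanlog[CONDITIONS],
                             cfg$bwt_sdlog[CONDITIONS])
  names(p_pos) <- CONDITIONS
  pos_ref <- if (reference_includes_mixed) c("do", "mixed") else "do"
  w <- cfg$diagnosis_mix[CONDITIONS]
  ref <- CONDITIONS %in% pos_ref
  list(sensitivity = sum(w[ref] * p_pos[ref]) / sum(w[ref]),
       specificity = sum(w[!ref] * (1 - p_pos[!ref])) / sum(w[!ref]))
}
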