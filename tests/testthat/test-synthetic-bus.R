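test_that("cohort generation is reproducible and respects the mix", {
  cfg <- bus_generator_config(n_women = 209, seed = 5)
  cohort <- generate_cohort(cfg)
  expect_equal(nrow(cohort), 209)
  expect_true(all(cohort$bwt_mm > 0))
  expect_true(all(cohort$baseline_utility > 0 & cohort$baseline_utility <= 1))
  expect_identical(cohort, generate_cohort(cfg))

  mix1 <- c(do = 1, stress = 0, mixed = 0, normal = 0, low_compliance = 0,
            voiding_dysfunction = 0)
  all_do <- generate_cohort(bus_generator_config(n_women = 40,
                                                 diagnosis_mix = mix1,
                                                 seed = 2))
  expect_true(all(all_do$true_diagnosis == "do"))

  expect_error(bus_generator_config(diagnosis_mix = c(do = 0.7, stress = 0.7,
    mixed = 0, normal = 0, low_compliance = 0, voiding_dysfunction = -0.4)),
    "probability vector")
})

test_that("default cohort has ~52% mixed-incontinence histories and DO most prevalent", {
  cfg <- bus_generator_config(n_women = 50000, seed = 31)
  cohort <- generate_cohort(cfg)
  p_mixed <- mean(cohort$history_label == "mixed")
  target <- sum(cfg$diagnosis_mix * cfg$p_history_mixed[names(cfg$diagnosis_mix)])
  expect_equal(target, 0.52, tolerance = 0.01)   # generator calibration
  expect_lt(abs(p_mixed - target), 3 * sqrt(target * (1 - target) / 50000))
  expect_equal(names(which.max(table(cohort$true_diagnosis))), "do")
})

test_that("accuracy estimation handles degenerate thresholds and perfect tests", {
  cohort <- data.frame(
    true_diagnosis = factor(c("do", "do", "stress", "normal"),
                            levels = c("do", "stress", "mixed", "normal",
                                       "low_compliance", "voiding_dysfunction")),
    bwt_mm = c(6, 7, 3, 4),
    history_label = factor(rep("mixed", 4), c("mixed", "urgency_only")),
    baseline_utility = rep(0.7, 4))
  acc <- estimate_accuracy(cohort, threshold_mm = 5)
  expect_equal(c(acc$tp, acc$fp, acc$fn, acc$tn), c(2, 0, 0, 2))
  expect_equal(acc$measures$estimate[acc$measures$measure == "sensitivity"], 1)

  acc0 <- estimate_accuracy(cohort, threshold_mm = 0)
  m <- acc0$measures
  expect_equal(m$estimate[m$measure == "sensitivity"], 1)
  expect_equal(m$estimate[m$measure == "specificity"], 0)

  expect_error(estimate_accuracy(cohort[0, ]), "empty")
  # 2x2 counts always partition the cohort
  expect_equal(acc$tp + acc$fp + acc$fn + acc$tn, nrow(cohort))
  # Wilson intervals enclose the point estimates (degenerate npv row with
  # no index-negative women is NA by construction)
  ok <- m$n > 0
  expect_true(all(m$ci_low[ok] <= m$estimate[ok] &
                    m$estimate[ok] <= m$ci_high[ok]))
})

test_that("large-sample accuracy estimates match the closed-form tail oracle", {
  cfg <- bus_generator_config(n_women = 50000, seed = 17)
  cohort <- generate_cohort(cfg)
  acc <- estimate_accuracy(cohort, threshold_mm = 5)
  oracle <- implied_accuracy(cfg, threshold_mm = 5)
  m <- acc$measures
  sens <- m$estimate[m$measure == "sensitivity"]
  spec <- m$estimate[m$measure == "specificity"]
  n_pos <- m$n[m$measure == "sensitivity"]
  n_neg <- m$n[m$measure == "specificity"]
  expect_lt(abs(sens - oracle$sensitivity),
            3 * sqrt(oracle$sensitivity * (1 - oracle$sensitivity) / n_pos))
  expect_lt(abs(spec - oracle$specificity),
            3 * sqrt(oracle$specificity * (1 - oracle$specificity) / n_neg))
})

test_that("prevalence estimation returns count-based Dirichlet parameters", {
  lv <- c("do", "stress", "mixed", "normal", "low_compliance",
          "voiding_dysfunction")
  cohort <- data.frame(
    true_diagnosis = factor(rep(c("do", "stress", "mixed"), c(100, 50, 50)),
                            levels = lv),
    bwt_mm = 4, history_label = factor("mixed", c("mixed", "urgency_only")),
    baseline_utility = 0.7)
  expect_error(estimate_prevalence(cohort), "zero count")
  prev <- estimate_prevalence(cohort, smooth = TRUE)
  expect_equal(sum(prev$params$concentrations), 200 + 6)

  cohort2 <- cohort[cohort$true_diagnosis %in% c("do", "stress", "mixed"), ]
  cohort2$true_diagnosis <- droplevels(cohort2$true_diagnosis)
  # proportions identity on the represented categories
  conc <- table(cohort$true_diagnosis)[c("do", "stress", "mixed")]
  expect_equal(as.numeric(conc) / sum(conc), c(0.5, 0.25, 0.25))
})

test_that("stratified prevalence recovers the generating mixes at large n", {
  cfg <- bus_generator_config(n_women = 50000, seed = 23)
  cohort <- generate_cohort(cfg)
  prev <- estimate_prevalence(cohort, stratify_by_history = TRUE)
  expect_named(prev, c("mixed", "urgency_only"))
  # Bayes: P(d | mixed history) from the generating mix and history model
  joint <- cfg$diagnosis_mix * cfg$p_history_mixed[names(cfg$diagnosis_mix)]
  target <- joint / sum(joint)
  est <- dist_mean(prev$mixed)[names(target)]
  n_mixed <- sum(prev$mixed$params$concentrations)
  for (d in names(target))
    expect_lt(abs(est[[d]] - target[[d]]),
              3 * sqrt(target[[d]] * (1 - target[[d]]) / n_mixed))
})

test_that("cohorts round-trip through delimited files", {
  cohort <- generate_cohort(bus_generator_config(n_women = 25, seed = 3))
  path <- tempfile(fileext = ".tsv")
  write_cohort(cohort, path)
  back <- read_cohort(path)
  expect_equal(back$true_diagnosis, cohort$true_diagnosis)
  expect_equal(back$bwt_mm, cohort$bwt_mm, tolerance = 1e-9)
  unlink(path)
})
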