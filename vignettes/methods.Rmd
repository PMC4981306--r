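---
title: "Model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`oabcea` evaluates how a diagnostic work-up should guide second-line
invasive treatment for women whose first-line conservative management of
overactive bladder (OAB) or urgency-predominant mixed urinary
incontinence (MUI) has failed. This vignette documents the model, its
assumptions, the parameters that drive it, and the numerical and design
choices the implementation makes.

## Decision problem and strategies

Each woman has a *true urodynamic state* in one of six categories:
detrusor overactivity (DO), urodynamic stress incontinence, urodynamic
mixed incontinence, normal bladder, low compliance only, or voiding
dysfunction only. Her *clinical-history label* is either urgency-only
(read as OAB) or mixed incontinence. Diagnostic options are the
urodynamic reference standard (assumed to reveal the true state),
bladder-wall-thickness (BWT) ultrasonography (index-test positive at
≥ 5 mm, read as DO; below threshold the scan cannot separate the urinary
syndromes and mixed-incontinence management is started), and clinical
history alone. Seven test–treat strategies are compared: each test for
all women, and each test restricted to women with a mixed-incontinence
(or OAB) history with the other subgroup managed on history alone.

## Treatment pathways

Management categories map to treatment sequences assembled from national
guidance:

* **OAB/DO** — botulinum toxin injections (chosen over neurostimulation
  with probability 0.750) or percutaneous tibial nerve stimulation.
  Failures proceed to a peripheral nerve evaluation; 67% receive a
  permanent neurostimulator implant, the rest the modality not yet
  given. Implant follow-up (revision before/after two years,
  maintenance, removal, each an exclusive alternative) is costed at the
  end of the horizon.
* **Stress incontinence** — sling surgery, then Burch colposuspension on
  failure, *unless any OAB treatment was previously given* (we apply
  this restriction globally, including inside the mixed pathway).
* **Mixed incontinence** — with probability 0.314 botulinum toxin
  precedes sling surgery; colposuspension follows a failed sling under
  the same restriction.
* **Normal bladder / low compliance only / voiding dysfunction only** —
  no further invasive treatment; these women remain symptomatic.

Effectiveness is a subjective-cure probability looked up by *(treatment,
true state)*. Interventions delivered to women whose true state is
normal bladder, low compliance only or voiding dysfunction only use the
most conservative elicited misdiagnosis proxy (0.143, the
botulinum-for-stress entry); this single parameter serves both roles, so
probabilistic draws stay coherent.

Further structural assumptions: up to three botulinum injections at
yearly intervals; botulinum can induce voiding dysfunction (probability
0.086) requiring self-catheterisation training; neurostimulation is a
12-session course with responders needing monthly maintenance sessions
thereafter; a maximum of two diagnostic tests per woman; and cure, once
achieved, persists to the end of the horizon (no tree path leaves a
cured state — tested structurally).

### The second diagnostic test

The source material states only that a second test may follow if a woman
remains symptomatic, and the exact wiring of the conditional-strategy
sub-trees is not reproduced in the main text. We adopt the following
rule, which the tree outline export (`format_tree()`, `tree_to_dot()`)
makes auditable: the second test is triggered by failure of the *first*
treatment of the assigned pathway. Where a test was already done at
entry it is a confirmatory repeat (cost only; urodynamics re-reveals the
same state and a repeat scan is assumed to reproduce the same BWT
classification). In the history-managed arm of a conditional strategy it
is that strategy's test and re-assigns management, with treatments never
repeated and colposuspension suppressed after OAB treatment. Clinical
history itself is free and uninformative on repeat, so the history-only
strategy incurs no test costs. The `single_test_only` scenario disables
the second test entirely.

### Event timing and discounting

Events sit on a yearly grid: entry test and first treatment in year 1,
repeat botulinum injections in years 2 and 3, failure assessment and any
second test in the year after a treatment cycle ends, implant follow-up
in year 5. Costs and QALYs in year 1 are undiscounted; year *t* ≥ 2
carries weight 1.035^−(t−1). Events that would fall beyond the horizon
are dropped, and cure contributions of undeliverable injections fold
into the failure branch, so probabilities still conserve. QALYs accrue
as utility × discounted years: the true-state utility until the year
before cure, then 0.920 (0.870 if botulinum-induced voiding dysfunction
occurred) to the horizon; uncured women retain their initial utility.
There is no half-cycle correction — the model is a decision tree on a
coarse yearly grid, not a Markov cohort.

### Botulinum course weighting

The three-injection course is costed with the drop-out weighting
1 + 0.80 + 0.736 (drop-outs of 20% and 8% after the first and second
injections), each injection discounted at its year, on every branch of
the course; the published analysis ties drop-outs to cost, not to cure.
Cure timing uses the disaggregated cure contributions 34%/52%/14% to set
the year the QALY stream switches to the cured utility.

## Parameters

All inputs live in `inst/extdata/default_config.yaml` and can be
overridden per entry (`load_parameters()` merges recursively; an entry
that specifies a distribution replaces its default wholesale).

* **Cure probabilities** (13 Beta rows) — meta-analyses and systematic
  reviews where available, expert elicitation otherwise (tagged
  `expert: true`; the `expert_low`/`expert_high` scenarios move exactly
  these rows to their interval bounds).
* **Pathway probabilities** (8 Beta rows) — modality choice, voiding
  dysfunction risk, implantation rate, implant follow-up event rates.
* **Unit costs** (10 Gamma rows, £ 2012–13) — NHS reference costs;
  ultrasonography and self-catheterisation training carry no interval
  and are fitted with sd = mean (shape 1).
* **Utilities** (7 Beta rows) — baseline utilities by urodynamic state;
  cured with/without side effects 0.920/0.870.
* **Accuracy and prevalence** — *synthetic stand-ins* (see below).
* **Economic settings** — discount rate 0.035/year, horizon 5 years,
  10,000 PSA iterations, incidence 54,000/year, research horizon
  10 years, willingness-to-pay grids to £100,000 per success (step £500)
  and £50,000 per QALY (step £250).

### Distribution fitting

Where effectively-treated counts exist, Beta shapes are the counts
themselves. Where only a mean and 95% CI are printed, the default fit
matches the mean exactly and equates the distribution's sd to the
normal-approximation interval width (hi − lo)/3.92; this reproduces the
published parameterisations to ~1%. A least-squares quantile-matching
alternative (`method = "quantile"`, optimising over the shape on a log
scale with the mean constrained, objective tolerance 1e-12) is provided
and verified against a brute-force grid search; for near-symmetric Beta
rows the two fits coincide, for skewed Gamma rows the moments fit is the
one consistent with the published tables. Three published effectiveness
rows print means that differ by one unit in the third decimal from their
own printed Beta parameters; the package carries the parameterisations
and their exact analytic means.

## Synthetic cohort generator

The accuracy and prevalence inputs of the primary cross-sectional study
are not redistributable, so `generate_cohort()` emulates a BUS-like
cohort: a six-category diagnosis mix (DO most prevalent, 40%), a
log-normal BWT per category (chosen for positivity and right skew; the
source does not describe BWT distributions), a per-category probability
of a mixed-incontinence history calibrated so the overall mixed share is
≈ 52%, and per-category baseline utilities from the published Beta
rows. Defaults are fixed on the 209-woman scale of the primary analysis
set. `estimate_accuracy()` (2×2 counts with Wilson 95% CIs at the 5 mm
threshold; reference positive = DO, optionally including mixed findings)
and `estimate_prevalence()` (Dirichlet concentrations = counts,
optional +1 smoothing, optionally stratified by history) close the loop;
parameter-recovery tests at n = 50,000 hold all estimates within three
Monte Carlo standard errors of the generating values, and a closed-form
log-normal tail oracle cross-checks the implied sensitivity/specificity.

What the generator does *not* emulate: bladder diaries, post-void
residual screening, recruitment exclusions, and measurement error in
urodynamics itself (the reference standard is treated as truth except in
the dedicated scenario). Passing tests therefore certify internal
consistency of the machinery, not the external accuracy values — those
must come from study data.

## Economic analysis

The frontier sorts strategies by expected cost, removes strictly
dominated entries, then removes extended-dominated entries until the
ICER sequence strictly increases; exact cost-and-effect ties keep the
strategy earlier in identifier order (deterministic, reproducible
reports). ICERs are presented rounded to the nearest £100 while full
precision is kept internally. A brute-force oracle (pairwise dominance
plus a greedy minimum-ICER climb) verifies the frontier on 1,000 random
instances.

The PSA draws one joint parameter vector per iteration — Beta, Gamma and
Dirichlet as configured — and evaluates every strategy tree on it, which
is what makes net-monetary-benefit comparisons and EVPI coherent. Each
parameter (and each Dirichlet component) has its own deterministic
sub-stream seeded from the master seed, so extending the iteration count
extends rather than reshuffles draws, and any strategy subset reproduces
its columns exactly. For speed, each tree is compiled once into its
root-to-leaf paths with branch probabilities as products of affine
parameter factors; a 10,000 × 7 PSA evaluates in well under a minute on
one CPU. The degenerate residual branch of the implant follow-up node
(1 − sum of four event probabilities) is clamped at zero in the
vanishingly rare joint draws that overshoot.

CEAF: at each willingness-to-pay the optimal strategy maximises *mean*
NMB; the curve reports the fraction of iterations in which that strategy
attains the iteration maximum, with ties split equally (an unbiased
probability under exact ties). EVPI per person is
`mean(max NMB) − max(mean NMB)`, clipped at zero against floating-point
residue; population EVPI multiplies by incidence × the discounted
10-year annuity factor (8.6077 at 3.5%). The EVPI "spikes" where the
optimal decision changes coincide with the frontier ICERs, which the
test suite verifies on deterministic toys.

## Deterministic scenarios

`uds_cost_low` (urodynamics at the all-HRG weighted average £173),
`sling_cost_double`, `cure_utility_low` (0.92 → 0.84),
`expert_low`/`expert_high` (elicited effectiveness rows to their
bounds), `single_test_only`, and `uds_accuracy_low_plus_diary`. For the
last, no alternative accuracy numbers are published; the packaged
values (urodynamic DO detection 0.92 with missed DO managed as mixed
incontinence, diary-sharpened history discrimination 0.30/0.90) are
configurable synthetic choices under `scenario_settings`. Scenario
application always returns a modified copy; the base parameter set is
immutable.

## Problem sizes and test scale

The packaged analyses use the model's own scale throughout: 7 strategy
trees of 162–888 enumerated paths, 10,000 PSA iterations, 201-point
willingness-to-pay grids, and 50,000-woman synthetic cohorts for
parameter recovery; the full test suite and the acceptance script each
complete in about a minute.

## Limitations

Headline published results depend on the primary study's accuracy and
prevalence tables, which are replaced here by synthetic stand-ins:
absolute costs, QALYs, CEAF probabilities and EVPI under the packaged
defaults are therefore indicative, while the structural results
(dominance pattern of ultrasonography, ordering of the urodynamics
strategies) have proven robust to them. The model is a decision tree,
not a state-transition model: no recurrence after cure, no mortality,
no adverse events beyond botulinum-induced voiding dysfunction, a fixed
5-year horizon, and an NHS perspective without personal costs.
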