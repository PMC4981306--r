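# oabcea

Decision-analytic cost-effectiveness model for **test–treat strategies in
women with refractory overactive bladder (OAB) or urgency-predominant
mixed urinary incontinence (MUI)**, from a UK NHS perspective.

When first-line conservative treatment fails, second-line invasive
treatment can be guided by the urodynamic reference standard, by
bladder-wall-thickness (BWT) ultrasonography (positive at ≥ 5 mm), or by
the clinical-history label alone (urgency-only vs mixed symptoms) — each
applied to all women or restricted to a history subgroup. `oabcea`
implements the seven resulting strategies as decision trees over a 5-year
horizon and compares them on expected discounted cost (£, 2012–13
prices), the probability of successful treatment (subjective cure), and
QALYs, with:

* **Parameter distributions** — Beta for probabilities/utilities, Gamma
  for costs, Dirichlet for multinomial splits; fitted from
  effectively-treated counts or from a mean and 95% CI.
* **Decision trees** — treatment pathways per assigned diagnosis
  (botulinum toxin / percutaneous neurostimulation / peripheral nerve
  evaluation / neurostimulator implantation for OAB; sling and
  colposuspension for stress and mixed incontinence), misdiagnosis
  effectiveness lookups, at most two diagnostic tests, and discounting at
  3.5%/year beyond the first year.
* **Economic analysis** — dominance-handled incremental
  cost-effectiveness frontiers; net monetary benefit
  `NMB(λ) = λ·E − C`; ICERs `ΔC/ΔE` between adjacent frontier members.
* **Uncertainty** — deterministic scenarios, a 10,000-iteration
  probabilistic sensitivity analysis (PSA) with one joint parameter draw
  per iteration, cost-effectiveness acceptability frontiers (CEAF), and
  expected value of perfect information, per person
  `EVPI(λ) = E_θ[max_s NMB_s(θ)] − max_s E_θ[NMB_s(θ)]` and scaled to the
  incident population (54,000/year over 10 years, discounted).
* **Synthetic cohorts** — the accuracy/prevalence inputs of the primary
  cross-sectional study are not redistributable, so a generator emulates
  a BUS-like cohort (true urodynamic diagnosis, log-normal BWT,
  history label, baseline utility) with known ground truth; packaged
  defaults are clearly labelled synthetic stand-ins.

## Worked example

```r
library(oabcea)

ps <- load_parameters()                    # published inputs + synthetic fixture
out <- evaluate_strategies(ps)
out[order(out$cost), ]
#>                      strategy cost qalys p_success
#>                       uds_all 4786 3.689     0.605
#>          uds_if_mixed_history 5164 3.685     0.625
#>            uds_if_oab_history 5188 3.676     0.625
#>   ultrasound_if_mixed_history 6176 3.636     0.602
#>     ultrasound_if_oab_history 6292 3.642     0.590
#>                ultrasound_all 6338 3.629     0.576
#>                   history_all 6735 3.638     0.596

frontier(out, "p_success")   # dominance-pruned ICER table
```

Treating every woman on urodynamic findings is the cheapest strategy
(£4,786 per woman, 60.5% successfully treated, 3.689 QALYs under the
packaged synthetic accuracy/prevalence inputs), and both ultrasound-only
and history-only management are dominated — more expensive and no more
effective — reproducing the qualitative pattern of the published
analysis. Probabilistic analysis:

```r
psa <- run_psa(ps, n_iterations = 10000, seed = 1)
ceaf(psa, 20000, "qalys")          # P(optimal strategy cost-effective) at £20k/QALY
evpi_per_person(psa, 20000, "qalys")
population_evpi(evpi_per_person(psa, 20000, "qalys"), 54000, 10, 0.035)
```

A full run (base case, scenarios, PSA, VOI, synthetic cohort) with CSV
outputs and a JSON manifest:

```r
run_analysis(out_dir = "results", seed = 1)
```

or from a shell:

```sh
Rscript inst/scripts/oabcea.R --out results --seed 1 --what basecase,psa
```

## Package layout

| Area | Files |
| --- | --- |
| Distributions | `R/distributions.R` |
| Parameter registry, scenarios | `R/parameters.R`, `inst/extdata/default_config.yaml` |
| Synthetic cohorts | `R/synthetic-bus.R` |
| Strategy trees | `R/tree-build.R`, `R/tree-eval.R` |
| Frontier / discounting / NMB | `R/econ.R` |
| PSA, CEAF, EVPI | `R/psa-voi.R` |
| Orchestration | `R/report.R`, `inst/scripts/oabcea.R` |

The methods vignette (`vignettes/methods.Rmd`) documents the model
structure, assumptions, parameter sources and numerical choices.
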