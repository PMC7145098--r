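# bfabm — agent-based simulation of breastfeeding behavior

Breastfeeding rates among low-income mothers — including participants of
the US Special Supplemental Nutrition Program for Women, Infants, and
Children (WIC) — fall well short of recommendations, and a mother's
infant-feeding choices unfold inside a dynamic system of knowledge,
hospital practices, family support and workplace constraints.  `bfabm`
simulates that system for a cohort of primiparous (first-time) WIC mothers
over the first six months postpartum, and estimates the population impact
of five common breastfeeding-promotion interventions: breastfeeding
education (KNWL), Baby-Friendly Hospital Initiative practices (BFHI),
postpartum breastfeeding counseling (COUL), partner support (PTR) and
supportive workplace environments (WP).

It is intended for maternal-and-child-health researchers and program
planners who want to compare hypothetical coverage scenarios ("what if 95%
of women delivered at a Baby-Friendly facility?") on a model calibrated to
observed baseline rates.

## The model in brief

Each simulated woman carries sociodemographics, a breastfeeding-knowledge
score $k \sim \mathrm{Beta}(\mu = 0.67, \sigma = 0.10)$, binary
intervention exposures, and scheduled barriers (lactation problems,
return to work).  She passes through three stages:

* **Intent** (pregnancy):
  $\operatorname{logit} P = \alpha + 1.17\,k \;(+\; \text{peer term})$
* **Initiation** (childbirth):
  $\operatorname{logit} P = \alpha' + \beta_i\,\text{intent} + 0.155\,\text{BFHI}$
* **Maintenance** (day 3 to month 6): a path-dependent
  `EXCLUSIVE > PARTIAL > FORMULA` state machine advanced in daily steps
  under three residual monthly transition rates, with barrier events
  resolved by support-dependent decision trees (both counselor and partner
  support: continue; one: step down; none: formula).  `FORMULA` is
  absorbing — breastfeeding cannot resume.

The intercepts $\alpha, \alpha'$, the exclusive-at-initiation share and
the three residual rates are calibrated against observed baseline rates
(intent 88.5%, initiation 93.0%, any/exclusive breastfeeding at 1/3/6
months) by exact-expectation RMSE grid search with a Nelder–Mead polish.
Outcomes are point prevalences averaged over 100 replicates of n = 3,845.

## Worked example

```r
library(bfabm)

model <- calibrate_baseline(seed = 1)   # warns: best fit on range floor
print(model)
#> Calibrated breastfeeding agent-based model
#>   reference cohort: n = 3845
#>   intent intercept    : 1.2584 (target 0.8850)
#>   initiation intercept: 1.0231 (target 0.9296)
#> Calibrated residual transition rates (per month):
#>   exclusive -> formula : 0.0553
#>   partial   -> formula : 0.0200
#>   exclusive -> partial : 0.0150
#>   exclusive share at initiation: 0.4398
#>   RMSE vs target: 3.866 percentage points

base <- run_scenario(model, scenario(name = "base"), replicates = 20, seed = 2)
ptr  <- run_scenario(model, package_scenario("PTR", 0.95), replicates = 20, seed = 3)
print(ptr)
#> Scenario 'PTR@0.95': 20 replicates of n = 3845
#>          intent initiation any_1m any_3m any_6m excl_1m excl_3m excl_6m
#> mean (%) 88.480     92.950 86.820  76.17 60.770  35.710  27.860  18.180
#> MC se     0.148      0.078  0.134   0.15  0.165   0.205   0.148   0.111

ptr$mean[["any_6m"]] - base$mean[["any_6m"]]
#> [1] 9.52
```

Reading this: the calibrated intercepts reproduce the baseline intent and
initiation rates exactly in expectation; the residual rates land on the
floor of their searched ranges because the scheduled barriers already
account for most breastfeeding attrition (the 3.9-point RMSE is dominated
by the steep observed month-1 drop, which the model smooths out — see the
limitations section of `vignette("bfabm-methods")`).  Raising partner
support from its 67.7% baseline to 95% lifts six-month any-breastfeeding
prevalence by about 9.5 percentage points in this model; intent and
initiation are untouched, as they should be for a postpartum lever.

Other entry points: `scenario_grid_standard()` (the full 31-scenario
single-lever and nested-package grid), `sensitivity_sweep()` (effect-
coefficient sweeps at 95% coverage), `synergy()` (package effect minus the
sum of single-lever effects), `write_outcome_tables()` (CSV export), and
the thin CLI `exec/bfabm` (`calibrate | simulate | experiment |
standard-grid | sensitivity`).

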