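---
title: "Modeling breastfeeding intent, initiation and maintenance with bfabm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling breastfeeding intent, initiation and maintenance with bfabm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`bfabm` is an agent-based simulation of infant-feeding decisions among
low-income (WIC-enrolled) first-time mothers, from late pregnancy through six
months postpartum.  Its purpose is comparative: given a cohort calibrated to
observed baseline breastfeeding rates, how much do population breastfeeding
outcomes improve when the coverage of common promotion interventions is
raised?  This vignette describes the model, its assumptions and tunable
parameters, the calibration machinery, and the limits of what the package's
tests demonstrate.

## The behavioral model

Each agent is one primiparous woman.  Her perinatal timeline has three
stages — pregnancy, childbirth/hospital stay, and postpartum — and her
breastfeeding follows a second, path-dependent state machine over
`EXCLUSIVE`, `PARTIAL` and `FORMULA` feeding.  Two principles shape all
dynamics:

* **Path dependence.** Once breastfeeding is reduced it cannot resume:
  transitions only ever step down the `EXCLUSIVE > PARTIAL > FORMULA`
  ordering and `FORMULA` is absorbing.  A woman who never initiates is
  formula-feeding for the whole horizon.
* **Stage-specific influences.** Knowledge (and optionally peers) act on
  prenatal *intent*; intent and a Baby-Friendly birth act on *initiation*;
  support from a lactation counselor, the partner and the workplace act on
  *maintenance* when barriers arrive.

**Intent.** During pregnancy each woman forms an intent to breastfeed with
probability

$$\operatorname{logit} P(\text{intent}) = \alpha +
\beta_k \cdot \text{knowledge} + \mathbf{x}'\boldsymbol\gamma +
w \cdot \bar{I}_{\text{peers}},$$

where knowledge is a score in $[0,1]$ (population distribution
Beta with mean 0.67, SD 0.10), $\beta_k = 1.17$ by default, the
sociodemographic coefficients $\boldsymbol\gamma$ default to zero (no
estimates exist for this population; the hooks accept nonzero values), and
$w$ is the peer-influence weight (default 0, see *Network*).

**Initiation.** At childbirth,

$$\operatorname{logit} P(\text{initiate}) = \alpha' +
\beta_i \cdot \text{intent} + \beta_b \cdot \text{BFHI},$$

with $\beta_b = 0.155$ for delivery at a Baby-Friendly facility and
$\beta_i = 2$ by default.  $\beta_i$ is not identifiable from marginal
rates alone; it controls how strongly intent and initiation are coupled and
is exposed as configuration.  Initiation is probabilistic rather than
deterministic in intent because the baseline initiation rate (93.0%)
exceeds the baseline intent prevalence (88.5%): some women without prenatal
intent must initiate.  Initiators start `EXCLUSIVE` with a calibrated share
$s$ and `PARTIAL` otherwise.

**Maintenance.** From the day after childbirth to six months, each woman's
status evolves in daily steps under two mechanisms:

1. *Residual hazards.* Three monthly transition proportions —
   exclusive→formula, partial→formula, exclusive→partial — absorb all
   reasons for reducing breastfeeding other than the explicit barriers.
   Monthly proportions $p$ are converted to per-day probabilities
   $q = 1 - (1-p)^{1/30.4375}$ so that compounding over one month
   recovers $p$.  The two exits from `EXCLUSIVE` compete within a day:
   a single uniform is compared with their cumulative per-step
   probabilities, which keeps each monthly marginal correct to first
   order.
2. *Barrier events.* Each woman may face a lactation problem (cumulative
   incidence 87.4% over the six months) and/or a return to work (9.1%
   within 0–2 months, 14.4% within 3–5 months; later returns and the
   not-employed majority produce no event inside the horizon).  Events are
   scheduled at cohort generation and resolved by decision trees:
   * *Lactation problem*: support from **both** a lactation counselor and
     a partner — continue unchanged; support from **exactly one** — step
     down one level; **no support** — step down two levels (straight to
     formula).  The no-support branch is not documented for this
     population; the default makes it harsher than one support, which
     preserves monotonicity of outcomes in support coverage, and its depth
     is configurable (`zero_support_steps`).
   * *Return to work*: a supportive workplace (break time, private space
     for pumping) — continue unchanged; otherwise step down one level
     (configurable, `rtw_steps`).

Barriers resolve before the same day's residual hazards — an arbitrary but
fixed ordering that is required for reproducibility and is immaterial at
daily resolution.

## Synthetic population

No individual-level records are distributed with the package, so cohorts
are synthesized from marginal distributions
(`default_parameters()$population`): age (normal 28.1 ± 6.4, truncated to
[15, 50] for plausibility), education (36.5% less than high school — the
education marginals as published sum to 101%, so the complement is used),
race/ethnicity (85% Hispanic), household income (48.4% at or below the
federal poverty level), the Beta knowledge score, and independent Bernoulli
exposures at the baseline coverages (BFHI 11.4%, counseling 78.1%, partner
support 67.7%, supportive workplace 52.1%).

Independence across fields is the default because no joint distribution is
available; the real population certainly carries sociodemographic
correlations that this synthesis does not reproduce.  Since the default
behavioral model attaches no effect to the sociodemographic fields, this
affects none of the shipped results, but users adding nonzero
sociodemographic coefficients should treat the independence assumption as a
limitation.

Two timing choices deserve emphasis because only cumulative or categorical
occurrence information is available:

* lactation-problem onset is drawn **uniformly** on (3 days, 6 months] —
  the minimal assumption given only a 0–6-month cumulative incidence
  (`lactation_window` in the registry makes the window configurable);
* return-to-work times are uniform within their reported category
  ([0, 2] or [3, 5] months).

The uniform-onset default is consequential; see *Limitations*.

## Peer network

Women preferentially connect with women of the same race/ethnicity.  The
package builds a homophilous random graph (`build_network()`): edges attach
one uniformly drawn endpoint to a same-ethnicity partner with probability
`homophily` (default 0.9) and to the other group otherwise, giving
approximately Poisson degrees (default mean 8).  Peer influence enters the
intent stage as the fraction of a woman's neighbours who intend to
breastfeed; isolated women fall back to the population fraction.  Because
no network statistics or influence magnitudes are available for this
population, the default peer weight is **zero**: the network is inert
unless a user opts in, and none of the shipped results depend on it.  With
a nonzero weight the intent draw is a two-pass computation (provisional
intents without the peer term, then final intents reusing the same
uniforms), a cheap one-step approximation to a self-consistent field.

## Calibration

Five scalars are calibrated against the observed baseline rates bundled in
`baseline_targets()` (breastfeeding outcomes of first-time mothers in the
Los Angeles County WIC population: intent 88.50%, initiation 92.96%, and
any/exclusive breastfeeding of 77.41/68.86/55.62 and 35.20/24.46/13.86
percent at 1/3/6 months):

1. the two logistic intercepts, by one-dimensional root finding on the
   *exact* cohort expectations (`calibrate_intercepts()`);
2. the three residual rates and the exclusive-at-initiation share, by RMSE
   grid search (`calibrate_rates()`).

The grid search does not simulate.  Conditional on a woman's covariates
and barrier schedule, her feeding status is a three-state Markov chain with
constant daily hazards interrupted by at most two deterministic barrier
maps, so expected population rates are computable exactly: state-occupancy
probabilities are propagated piecewise-analytically between events
(geometric decay within intervals, closed-form coupling of the
exclusive→partial flow) and averaged over the cohort.  This evaluator
(`expected_rates()`) is noise-free — equivalent to a replicate mean with
infinitely many replicates — which makes the search well-posed and fast; a
stochastic grid mode (`method = "simulated"`) is retained as a
cross-check, and the test suite verifies that the exact evaluator agrees
with large-cohort simulation.

Because outcome rates are *linear* in the exclusive share $s$
(a mixture of an all-exclusive and an all-partial start), $s$ is profiled
out in closed form at every grid point.  The search itself is a 10-point
coarse grid per rate over the ranges 0.004–0.08, 0.02–0.5 and 0.015–0.3,
followed by a 5× finer pass spanning one coarse step around the incumbent,
followed by a bounded multi-start Nelder–Mead *polish* from the best five
grid points.  The polish matters: the three rates trade off along shallow,
near-flat ridges of the RMSE surface (the exclusive→formula rate in
particular is weakly identified against the other two), so a pure grid
argmin can sit several steps from the optimum at a negligible RMSE
difference.  With the polish, parameter-recovery experiments on synthetic
targets recover known rate triples essentially exactly.  Ties break toward
the smallest rates; a best fit on the range boundary triggers a warning.

## Experiments

A `scenario()` raises intervention levers above baseline: the knowledge
lever shifts the Beta mean (its levels 0.80/0.90/0.95 are score means, with
SD kept at 0.10, clipped to the Beta feasibility bound if needed); the four
coverage levers are *topped up* — currently unexposed women flip with
probability $(target - base)/(1 - base)$ — so existing exposures are
preserved and scenarios are comparable at fixed seeds.  `run_scenario()`
averages the eight outcome rates (intent, initiation, any/exclusive at
1/3/6 months, as *point prevalences* of the feeding status) over 100
replicates, resampling a fresh cohort of n = 3,845 per replicate by
default.  Replicate seeds derive deterministically from the base seed, so
running two scenarios with the same seed yields common random numbers
(sharper contrasts, used throughout the test suite), while different seeds
give independent runs (used for headline reproduction).

"Any breastfeeding at month *t*" is evaluated as the point prevalence of
exclusive-or-partial status at *t*.  An ever-breastfed reading would be
non-increasing only trivially and could not decline between months, which
the reference trajectories clearly do; point prevalence is the only
internally consistent reading.

`sensitivity_sweep()` varies one of the two effect coefficients
($\beta_k \in \{1.0, 1.17, 1.25, 1.5\}$ or
$\beta_b \in \{0.1, 0.155, 0.25, 0.5\}$) with every lever at 95%.  For
each value the intercepts are **re-calibrated** against the baseline
intent/initiation rates before the scenario is applied, so every swept
model is anchored to the same observed baseline and the sweep isolates the
coefficient's effect on the *intervention response* rather than on the
baseline.  (Without re-calibration, changing a coefficient would move the
baseline itself, confounding the comparison.)

## Numerical and reproducibility choices

* **Clock.** Daily steps with a 30.4375-day month; childbirth at day 0,
  hospital stay through day 2, postpartum life from day 3; evaluation at
  days 30, 91 and 183.  Daily granularity makes the 1–2-day hospital stay
  and the month-1 evaluation representable with negligible discretization
  error.
* **RNG.** All randomness flows through explicit seeds.  Within a run,
  uniforms are generated for agents in id-sorted order and assigned by id,
  so each woman's draws depend only on the seed and her id — results are
  bitwise invariant to the order of cohort rows (verified by permutation
  tests).
* **Degenerate inputs.** Monthly rate 1 converts to a per-step probability
  of 1 with a warning; decision trees called on non-breastfeeding statuses
  are warning no-ops; infeasible Beta moments and non-normalized category
  probabilities are rejected with the violated bound named; cohorts with
  missing required fields are rejected before simulation.
* **Problem sizes.** The shipped defaults — 100 replicates of n = 3,845
  per scenario, a 1,000-point coarse calibration grid — run in about a
  minute each on a single CPU.  The test suite exercises the same code
  paths at these scales for the headline checks and at reduced scales
  (hundreds of agents, a few replicates) for structural properties.

## Limitations

* **The baseline components do not fully compose.**  The bundled target
  trajectory falls steeply in month 1 (initiation 92.96% to any-BF 77.41%)
  and then shallowly (to 68.86% and 55.62% at months 3 and 6).  Under a
  uniform lactation-problem onset, barrier-driven losses are spread evenly
  — roughly 4–5 percentage points of any-BF per month given the decision
  trees and an 87.4% cumulative incidence — which is *more* than the
  entire observed month-3-to-6 decline and far *less* than the observed
  month-1 drop.  No setting of the three residual rates can reconcile
  this: calibration drives the partial→formula and exclusive→formula rates
  to their range floors and still leaves a residual misfit concentrated at
  month 1 (RMSE ≈ 3.8 percentage points, with the 1-month any-BF rate
  about 8 points high and the 6-month rate about 4 points low).  A
  front-loaded onset distribution (clinically, most lactation problems
  arise in the first weeks) fits the month-1 drop better but then
  overshoots the months-1–3 decline; the package keeps the assumption-poor
  uniform default and reports the misfit rather than absorbing it into an
  onset parameter.  Comparative conclusions (lever effects, package
  synergy) are more robust than absolute levels: six-month effects depend
  on the cumulative barrier incidence, not its timing.
* **Decision-tree effect sizes are strong.**  With one source of support
  producing a step-down at an 87.4%-incidence event, the postpartum
  support levers (counseling, partner, workplace) move six-month rates
  somewhat more than the reference effects, and the exclusive-breastfeeding
  response to partner support is correspondingly high.  The tree branches
  beyond the documented both/one-support rules are reconstructed, not
  observed.
* **What passing tests do and do not show.**  The synthetic cohorts
  reproduce marginal distributions, not joint structure; the network is a
  stylized homophilous random graph with no empirical degree or influence
  data; barrier timing within its windows is assumed.  Green property
  tests demonstrate internal consistency (monotone trajectories, exact
  expectations, recovery of known parameters, reproducibility), not
  fidelity to any real cohort beyond the calibrated marginal rates.
* Multiparous women, peer counseling as an intervention, infant health,
  and milk-supply physiology are out of scope.
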