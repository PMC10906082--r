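---
title: "Methods: a semi-Markov model for treatment-sequencing cost-effectiveness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a semi-Markov model for treatment-sequencing cost-effectiveness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqcea)
```

## The question the model answers

High-priced targeted agents such as the ALK inhibitors brigatinib and
lorlatinib are taken continuously until progression. For ALK-positive
non-small cell lung cancer this poses a sequencing question: is it worth
*starting* with the expensive inhibitors (and falling back to chemotherapy on
progression), or should they be *reserved* for use after first-line
chemotherapy fails? The two strategies compared are:

* **Strategy A** — brigatinib → lorlatinib → platinum–pemetrexed
  chemotherapy → docetaxel → best supportive care (BSC) → death;
* **Strategy B** — platinum–pemetrexed chemotherapy → brigatinib →
  lorlatinib → docetaxel → BSC → death.

Each strategy is evaluated as a cohort over a lifetime horizon, accumulating
discounted direct costs and quality-adjusted life-years (QALYs), and the two
are compared by the incremental cost-effectiveness ratio
\(\mathrm{ICER} = \Delta\mathrm{cost}/\Delta\mathrm{QALY}\) against a
willingness-to-pay (WTP) threshold of \$150,000 per QALY.

## Model structure

The model is a **semi-Markov cohort model** with six mutually exclusive
states: treatment lines 1–4, BSC, and death, on 1-month cycles. Per-line
progression risk is *time-in-state dependent*: each line carries a parametric
progression-free survival (PFS) law whose clock restarts at line entry, so the
state space is expanded into **tunnel strata** indexed by cycles since entry.
The per-cycle probability of leaving a line after `k` completed cycles is the
survival-ratio transition probability

\[
tp(t, u) = 1 - \frac{S(t)}{S(t-u)}, \qquad t = (k+1)u,
\]

which for the Weibull parameterization used here,
\(S(t) = \exp(-\lambda t^{\gamma})\), reduces to the closed form
\(1 - \exp\{\lambda(t-u)^{\gamma} - \lambda t^{\gamma}\}\). The same ratio
definition is applied to every other family, being the unique generalization
consistent with the survivor function.

Death from an active treatment line occurs at the age-matched background
rate: the annual probability from a life table is converted to a monthly
probability \(1-(1-q)^{1/12}\). Within a cycle death is applied **before**
progression (progression is scaled by the probability of surviving the
cycle); the model is silent on intra-cycle ordering in most published
descriptions, so this competing-risk convention is isolated in
`cycle_transition()` and documented rather than buried. In BSC, the per-cycle
death probability is the larger of the BSC overall-survival transition
probability (clock restarting at BSC entry) and background mortality, so BSC
patients never die more slowly than the general population.

Costs and utilities accrue at the beginning of each cycle with **no
half-cycle correction**, and both are discounted at 3% per year,
\(d(c) = 1.03^{-c/12}\). Grade ≥ 3 adverse events are one-time effects: each
line's expected adverse-event cost and QALY decrement (incidence-weighted) is
charged to the cohort fraction entering that line. A configuration switch
(`ae_timing = "model_start"`) instead charges the full expected burden once
at model start, the literal reading of "applied to the first cycle of the
model"; the per-line-entry default reflects that each line's adverse-event
profile comes from its own trial.

The lifetime horizon is realized as an age cap of 100 years; simulation also
stops once death occupancy exceeds \(1 - 10^{-6}\). The cohort starting age
defaults to 58 years (a typical ALK-positive NSCLC trial population; the
source analysis never states one) and is configurable.

## From published figures to survival laws

Trial evidence enters as digitized Kaplan–Meier curves with numbers-at-risk
tables. `reconstruct_ipd()` implements a Guyot-type allocation: within each
interval between risk-table times, events are placed at the digitized drop
times and censorings are spread uniformly, iterating the censoring count
until the end-of-interval number at risk is matched exactly. Digitized
survival values are first clipped to be non-increasing (hand-digitized curves
wobble); events precede censorings at tied times; after the last risk-table
time no interior censoring is assumed and the residual cohort is
administratively censored at the last coordinate (rescaled to a reported
total event count when one is supplied).

`fit_parametric()` maximizes the right-censored log-likelihood
\(\sum_{\text{events}} \log f(t_i) + \sum_{\text{censored}} \log S(t_i)\)
for seven families — exponential, Weibull, gamma, Gompertz, generalized
gamma, log-normal, log-logistic — under explicit parameterizations (see
`?parametric_survival`), with log-transformed positive parameters,
moment-based multi-starts, and a 1e-8 convergence tolerance on the
log-likelihood; the exponential uses its closed form, rate = events / total
follow-up. `select_model()` screens families by AIC or BIC, breaking ties by
parsimony and then by a fixed canonical family order. Because the source
analysis does not state which family won for each treatment line, the
configuration accepts any family per line rather than hard-coding one.

## The synthetic study conditions

No trial data ship with the package; the `synthetic_data` functions generate
every input from known ground truth:

* `simulate_km()` draws event times by inverse-CDF sampling, censors
  administratively, and emits a monthly digitization grid with a 6-monthly
  risk table (the digitization density of published figures is unknown, so
  these are configuration, not fact).
* The generator's first-line laws target 12-month PFS of 0.67 (ALK
  inhibitor) and 0.43 (chemotherapy), echoing the trial report the analysis
  emulates; lorlatinib, docetaxel and the BSC overall-survival law (median
  6 months) are plausible synthetic choices.
* `make_base_case_config()` assembles the full two-strategy configuration.
  Printed inputs are used verbatim: utilities 0.71/0.67/0.59/0.46 by line
  (BSC 0.46), 3% discounting, \$150,000/QALY WTP, the 1.72 m²/65 kg/70 mL/min
  dosing profile, and a brigatinib cycle cost of \$20,143.91 — the upper end
  of the published one-way range, taken as the base case because the
  analysis varied inhibitor prices downward only. All other unit prices and
  the adverse-event profiles are synthetic stand-ins.
* A synthetic Gompertz–Makeham life table supplies background mortality
  (annual probability ≈ 0.008 at age 58).

### Calibration

`calibrate_to_base_case()` adjusts *only unprinted* quantities until both
strategies' discounted totals match the published base-case table
(\$219,712 / 0.70 QALYs and \$196,513 / 0.76 QALYs) within 1%:

1. **QALY targets.** Lines 2–4 are pinned at fixed plausible mean sojourns
   (strategy A: 1.2/0.5/0.5 months; strategy B: 3.2/0.8/0.5), and each
   strategy's first-line sojourn is solved by root-finding (QALYs are
   monotone in it). A design with one *uniform* hazard multiplier per
   strategy is provably infeasible: the higher-QALY arm would then spend
   uniformly longer in every line and hence accrue more of every drug, so no
   positive shared prices could make the lower-QALY arm the costlier one, as
   the target table requires.
2. **Cost targets.** With the traces fixed, cost totals are linear in cycle
   costs, so the unprinted lorlatinib and BSC cycle costs are solved exactly
   from the two cost equations (2×2 in the discounted exposures), with a
   bounded least-squares fall-back over all unprinted costs.

Utilities, the discount rate and the brigatinib cycle cost are never touched,
so printed inputs cannot be silently altered. The sojourn design also keeps
each drug's contribution to the incremental cost single-signed and modest —
the \$23,199 increment is not a cancellation of large opposing terms — which
is what makes the published robustness claim (dominance across all
sensitivity analyses) reproducible rather than knife-edge.

The calibrated world is synthetic: it reproduces the published *totals*,
not the (unavailable) trial-fitted survival parameters or prices. Results on
it validate the machinery and the printed arithmetic, not the underlying
trials.

## Sensitivity analysis

One-way analysis (`one_way_dsa()`) re-runs the model at each parameter's low
and high bound (default ±20% of base; published bounds override, e.g.
brigatinib's \$16,115.128–\$20,143.91 per cycle; inhibitor prices vary
downward only) and tabulates the ICER spread, tornado-style.

The probabilistic analysis (`run_psa()`) draws 1,000 simultaneous parameter
assignments: gamma distributions for costs and beta for utilities, each
moment-matched to (base, SE = 20% of base) — the distributional assignment
follows decision-modelling convention since the source supplement is
unavailable — with one draw per parameter shared by both strategies
(parameters are global, not per-arm). Survival laws are held fixed by
default, matching the fixture assumptions behind the headline probabilistic
claim; varying them requires explicitly adding `survival.*` paths to the
range table, which routes the analysis through full per-iteration cohort
re-runs. When no varied parameter touches survival, settings or the life
table, the cohort traces are computed once and only the (linear)
accumulation step is repeated per iteration — an exact shortcut, since
occupancy depends only on survival and mortality inputs. `ceac()` converts
the draws to cost-effectiveness acceptability curves via net monetary
benefit, `qalys × WTP − cost`, splitting ties equally; `ce_scatter()` emits
the incremental cloud.

## Numerical choices and degenerate inputs

* Occupancy vectors conserve probability to 1e-10 per cycle by construction;
  the invariant suite asserts it.
* `S(t-u) = 0` (an exhausted risk set far in the tails) yields a transition
  probability of 1 with a warning.
* All-censored data are refused by the fitter ("no events"), and the KM
  generator refuses a non-positive censoring time outright.
* Risk tables inconsistent with any non-negative allocation abort
  reconstruction with the offending interval named.
* Model-selection ties (criterion within 1e-9) resolve to fewer parameters,
  then canonical family order.
* PSA iteration seeds derive deterministically from (master seed,
  iteration), so runs are bitwise reproducible and individual iterations can
  be replayed in isolation.
* Beta moment-matching infeasibility (SE² ≥ mean(1−mean)) falls back to a
  uniform draw on [low, high] with a warning.

## Problem sizes used in the shipped checks

The test suite exercises parameter recovery at n = 500 (through the full
digitize → reconstruct → refit pipeline, 15% tolerance) and n = 2,000 per
family (direct fits, 10% tolerance); the probabilistic analysis uses the
published 1,000 iterations. These sizes echo realistic trial cohorts and
standard PSA practice.

## What passing tests do and do not show

The synthetic generator reproduces the *shape* of the published inputs —
monotone digitized curves with risk tables, a monotone life table, printed
utilities/prices where available — but not patient covariates, non-squamous
histology subgroups, intracranial endpoints, interval-censoring artefacts of
digitization, or the true (unpublished) fitted survival parameters. Passing
tests therefore demonstrate correctness of the reconstruction, fitting,
cohort and economic machinery under known ground truth, and reproduction of
the published worked-example arithmetic and probabilistic claim under
calibrated synthetic conditions; they are not an external validation of the
source analysis against real-world outcomes.

## Known limitations

* Partitioned-survival variants, microsimulation, treatment waning and
  dose-reduction are out of scope.
* The literal identity of the platinum agent (cisplatin versus carboplatin)
  differs between the source's figure and text; the dosing module supports
  both (`per_bsa` and `carboplatin_auc` rules) and the fixture uses the
  carboplatin form without asserting which the source used.
* Whether active-line PFS curves should contain death events (rather than
  death being background-only) is unresolved in the source; the stated
  background-only rule is implemented.
* The published ICER (−\$400,722.09/QALY) is not the quotient of the
  published rounded increments; the package reports full-precision quotients
  and does not attempt to match that figure.
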