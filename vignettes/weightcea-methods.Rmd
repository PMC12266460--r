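---
title: "Methods: a Markov cohort cost-effectiveness model for weight-loss maintenance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov cohort cost-effectiveness model for weight-loss maintenance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(weightcea)
```

## The decision problem

A behavioural trial for rural adults with obesity compared telephone-based
individual coaching against an education-only control for *maintaining* an
initial weight loss. Coaching costs more to deliver; participants who keep
more weight off report better health and somewhat lower out-of-pocket
healthcare spending. `weightcea` formalises the trade-off as a
cost-utility analysis from the program/participant perspective: per-arm
discounted costs and QALYs, their increments, and the incremental
cost-effectiveness ratio judged against a $150,000/QALY willingness-to-pay
threshold.

## Model structure and assumptions

The health model is a discrete-time Markov cohort model over four states
defined by percent weight reduction from the month-0 baseline:

* `lt5` — limited or no loss (< 5% below baseline, including any gain),
* `m5_10` — moderate loss (5–10% inclusive at both printed endpoints),
* `gt10` — large loss (> 10%),
* `dead` — death or loss to follow-up, the single absorbing state.

Assumptions worth making explicit:

1. **First-order Markov dynamics.** A participant's next state depends only
   on the current state; individual weight-history effects beyond the
   current category are ignored.
2. **Within-trial matrices are taken at face value.** Months 0–4, 4–16 and
   16–22 are three observed segments; each segment's empirical matrix is
   applied as one block, so the trace reproduces the observed occupancies at
   months 4, 16 and 22 *exactly* (an anchoring property the tests assert).
   The 4–16 segment spans two nominal cycles but is estimated and applied
   as a single observed block.
3. **Last-observed extrapolation.** Beyond month 22 the month-16→22 matrix
   (a 6-month interval, matching the cycle length) is applied once per
   cycle. This is a deliberately conservative choice: it freezes late-trial
   behaviour rather than projecting continued improvement.
4. **Uniform background mortality.** No within-trial deaths are modelled
   (the trial recorded none). Post-trial, a single annual probability —
   identical across states and arms — is converted to a per-cycle
   probability by constant-hazard rescaling and overlaid multiplicatively
   as a competing risk, leaving the conditional alive-to-alive dynamics
   untouched.
5. **Utilities are raw survey scores.** HT-VAS and SF-36 general-health
   scores (0–100) divided by 100 serve directly as utilities — alternative
   QALY measures, not tariff-mapped EQ-5D utilities. The dead state has
   utility 0 and cost 0.

## Parameters

| Parameter | Default | Units | Rationale |
| --- | --- | --- | --- |
| Cycle length | 6 | months | fixed by the model design; assessment spacing |
| Horizon | 70 | months | 22-month trial + eight 6-month post-trial cycles (~5 years of projection) |
| Discount rate | 0.03 | /year | conventional base case; 0.01/0.05 in the one-way analysis |
| Annual mortality/attrition | `1 − 0.957^(1/5)` ≈ 0.00875 | probability/year | calibrated so the 5-year cumulative absorbing risk is 4.3% |
| WTP threshold | 150,000 | USD/QALY | conventional US benchmark |
| QALY window start | 10 | month | makes the end-of-trial window (months 10–22) span exactly one year, so end-of-trial QALYs live on a 0–1 scale |
| Program costs | packaged ledger | USD | per-phase line items divided by arm size (153 control, 149 coaching), rounded half-up to the cent |
| State economics | packaged table | USD/month, score points | state-conditional means observed at the end of the maintenance phase |

Whether the published model applied the month-70 grid or projected to month
82 ("five years after month 22") is not decidable from the printed tables;
`horizon_months` is configurable and validated to sit on the 6-month grid.
Similarly, both the direct 6-month path and the annualize-then-rescale path
(`to_annual()` + `rescale_probability()`) are implemented; the engine uses
6-month matrices directly by default.

## Accumulation and discounting

Costs and QALYs accumulate per stored trace interval, clipped to an
analysis window: occupancy-weighted state value × interval duration ×
discount factor `(1.03)^(−t/12)` at the interval end. Program delivery
costs are added undiscounted (they are incurred within the first 16
months). By default there is no half-cycle correction — attribution at
interval end, matching a discrete spreadsheet cohort model — and a
`half_cycle` flag switches to midpoint discounting with endpoint-averaged
occupancy for users who want to probe the difference. Setting the rate to 0
reduces the accumulators to plain sums (tested exactly), and both
accumulators are linear in occupancy and in state values.

The 5-year cost window is months 0–70; the 5-year QALY window is months
10–70 (60 months, so the scale is 0–5 QALYs). The end-of-trial windows are
months 0–22 and 10–22. The exact month composition behind the published
end-of-trial QALY values is not documented; the 10–22 window is this
package's choice, made once and kept.

## The synthetic cohort generator

The generator exists so every downstream stage is testable without
participant-level study data. It emulates:

* arm sizes 153/149, 82.7% female, age ~ N(55.4, 10.3²) truncated to the
  21–75 eligibility window, baseline weight ~ N(99.8, 14.6²) kg truncated
  to 55–180 kg;
* month-16 and month-22 state occupancies matching the observed per-arm
  targets (marginally exact in expectation; ±0.02 at n = 10,000/arm by the
  binomial bound, tested);
* state-conditional survey scores: truncated normal on [0, 100], SD 18
  points — a typical dispersion for these instruments in trial populations;
* state-conditional monthly costs: zero with probability 0.2, else gamma
  with coefficient of variation 1.0, positive mean inflated so the overall
  mean equals the configured state mean;
* missing-completely-at-random survey/cost fields at rate 0.05.

Trajectories are drawn as category paths month 4 → 16 → 22. Consecutive
marginals are coupled by iterative proportional fitting (IPF) of a
diagonal-favouring prior (stay-weight 4 vs 1), so the joint respects both
marginals while keeping trajectories sticky; the implied 16→22 kernel is
exactly recoverable by the estimator (a parameter-recovery test at
n = 10,000/arm). The month-4 occupancy, not printed in any published table,
is set once to (0.30, 0.30, 0.40) for both arms — both arms received the
same active-loss program, and large early losses are characteristic of that
phase. Percent loss within a category is uniform on the category interval,
with the open > 10% category truncated at 25% loss (a plausible trial
range; this affects only the kilogram weights, never the categories).

What the generator does **not** emulate: real within-person correlation of
scores over time, informative missingness, dropout, within-trial mortality,
measurement error in weights, or any group-coaching arm. Tests that pass on
synthetic data therefore validate the *pipeline arithmetic and its
statistical contracts*, not the clinical conclusions on real data: the
generator's transition structure is an IPF coupling, whereas the published
matrices came from actual paired observations the printed tables do not
fully disclose. Consequently the package reproduces the published
*arithmetic* (cost division, ICER ratios, ±20% repricing) exactly, while
absolute 5-year costs/QALYs and modeled occupancies depend on unpublished
inputs and are validated structurally instead (anchoring, conservation,
monotone absorption, matrix-power composition).

## Uncertainty analysis

**PSA.** Per replication, state utilities are redrawn from normals
truncated to [0, 100] centred at the base-case means with a standard-error
scale SD (18/√100 = 1.8 points, treating ~100 respondents per state), and
state monthly costs from zero-inflated gammas (zero probability 0.2, CV
1.0) whose means equal the base case. Draws are *shared across arms* within
a replication: arm differences then flow through occupancy alone, which is
what makes the cost-effectiveness fraction a statement about the model
rather than about independent noise. Transition probabilities are not
resampled — the uncertainty analysis targets the economic parameters; a
Dirichlet extension over matrix rows would be straightforward but is not a
default behaviour. 1,000 replications run in well under a minute.

**One-way analysis.** Eleven deterministic scenarios: the recomputed base
case, each arm's phase-2 program cost ±20% (repriced per participant to
the cent), all medication costs ±20%, all other-healthcare costs ±20%, and
discount rates 1% and 5%. Pure cost scenarios leave incremental QALYs
bit-identical to the base case (tested); scenario ICERs satisfy
ICER × ΔE = ΔC by construction (also tested).

## Numerical choices

* Category boundaries: ties at exactly 5% and 10% loss go to the moderate
  bin, matching the printed category labels (< 5%, 5–10%, > 10%).
* Empty origin states during estimation become self-loop rows with a
  warning — conservative, preserves row-stochasticity; the month-0 origin
  rows are structurally empty (everyone starts at baseline) and are
  estimated quietly.
* Row-stochasticity is validated at 1e-9 everywhere; the dead row is forced
  absorbing after every operation.
* Currency is rounded half-up to the cent (`floor(x·100 + 0.5)/100`), the
  accounting convention, rather than R's round-half-even.
* The truncated-normal MLE maximises the renormalised likelihood directly
  (Nelder–Mead on (mean, log sd), moment start, relative tolerance 1e-8);
  the gamma MLE delegates to `fitdistrplus::fitdist()` with moment-based
  starts. Degenerate inputs (constant samples, all-zero costs) return
  explicit point-mass specifications instead of failing.
* Truncated-normal sampling is inverse-CDF with exactly one uniform per
  draw, so the RNG stream is invariant to the parameter values — a
  prerequisite for the "zero-variance PSA equals the base case" exactness.

## Problem sizes

The test suite uses trial-sized cohorts (302 records) for end-to-end
checks, 10,000-per-arm cohorts for convergence and recovery bounds, 10,000
draws for distribution-fitter recovery, and the full 1,000-replication PSA
once; the whole suite runs in about 40 seconds on one core.

## Known limitations

* The extrapolation freezes month-16→22 dynamics; if real-world regain
  accelerates or plateaus, 5-year projections shift accordingly.
* Mortality is age- and sex-invariant; a life-table overlay by individual
  characteristics is out of scope.
* Utilities are unmapped 0–100 scores; QALYs are therefore "alternative
  measure" QALYs and not comparable across studies using tariff utilities.
* Costs are assumed to be in constant dollars on input; no inflation
  machinery is included.
* The analysis is strictly pairwise (two arms); efficiency frontiers over
  more strategies are not implemented.
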