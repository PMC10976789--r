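---
title: "Model structure, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vabpcea)
```

## The decision problem

`vabpcea` models the cost-effectiveness of ceftolozane/tazobactam (CTZ/TAZ)
against meropenem (MEPM) as first-line therapy for ventilated
hospital-acquired / ventilator-associated bacterial pneumonia (vHABP/VABP)
from the perspective of the Japanese healthcare payer. The comparison is a
hybrid of two standard structures:

1. **An acute-phase decision tree.** Each patient is treated first line for
   about 8 days in the ICU under mechanical ventilation. The episode ends in
   one of three ways: clinical cure, death, or escalation to second-line
   therapy (the residual probability). Second-line therapy adds amikacin to
   the first-line drug for 7 days and 21 additional ICU days, and again ends
   in cure, death, or long-term ICU care (one terminal ICU month, then
   death). Cured patients on either line are discharged home or spend one
   month on a general ward (with a 7.6% per-stay ward mortality) before
   discharge.
2. **A long-term Markov cohort model.** Survivors enter a three-state
   discrete-time model — `DischargedAlive`, `InWard` (one cycle), `Dead`
   (absorbing) — and die at an age-dependent background rate until the
   5-year horizon, measured from treatment start, is reached.

Costs are direct medical costs only: drug acquisition (daily tariff ×
administration days), hospitalization (per-arm scalar inputs), mechanical
ventilation under a two-tier daily tariff (9,500 yen/day through day 14,
8,150 yen/day afterwards — first-line ventilation falls in the early window,
second-line ventilation is past day 14 by construction), expected
adverse-event treatment cost (incidence × per-event cost, plus the
amikacin-attributable acute renal failure on second line), and lump-sum
long-term ICU and ward care. QALYs weight time in state by annual utilities:
−0.39 for ventilated ICU care (a state judged worse than death), 0.77 for
the ward month, 0.80 after discharge.

The headline outputs are the incremental cost, incremental QALYs, the ICER
(computed from unrounded increments), and net monetary benefit at the
Japanese willingness-to-pay threshold of 5,000,000 yen/QALY.

## Parameters that matter, units and defaults

All inputs live in a single validated object (`reference_inputs()`, or a
YAML/JSON file via `load_parameters()`); rates are proportions internally
(a `units: {rates: percent}` key converts on load), money is in yen,
durations in days, utilities per year.

| Group | Key defaults |
|---|---|
| Efficacy (1st line) | cure 0.606 / 0.571, mortality 0.201 / 0.255 (CTZ/TAZ / MEPM), with 95% bounds |
| Efficacy (2nd line) | cure 0.568 / 0.528, mortality 0.241 / 0.306 |
| Discharge split | 50.6% / 56.7% of cured patients discharged directly |
| Durations | admin 8 / 8.23 d (1st), 7 d (2nd); ICU 28 / 24 d (+21 d 2nd); ventilation 12 / 13 d (1st), 12 d (2nd) |
| Costs | drug 36,414 / 2,589 / 714 yen/day (CTZ/TAZ, MEPM, AMK); hospitalization 2,136,960 / 2,063,280 (1st) and 350,340 / 358,020 (2nd); long-term ICU and ward care 495,000 each |
| Utilities | −0.39 ICU-ventilated; 0.80 discharged; 0.77 ward |
| Settings | 5-year horizon, 30-day cycles, 2%/yr discount (0–4% sweep range), WTP 5,000,000 yen/QALY, start age 65, ward mortality 7.6% |

Points worth flagging:

* **Second-line efficacy.** The model carries *printed* second-line rates as
  defaults. A derivation rule (`use_derived_second_line = TRUE`) instead
  reduces first-line cure by 10% and raises mortality by 20%
  (`derive_second_line()`). The two do not coincide exactly (0.568 vs
  0.606×0.9 = 0.545); the package keeps both and defaults to the printed
  values, which the derived mortality (0.2412, 0.306) happens to match.
* **Mortality interpretation.** Trial mortality is treated as marginal over
  all treated patients (all-cause mortality over everyone randomized to the
  line), so the second-line branch receives `1 − cure − mortality`. A
  conditional-on-non-cure reading is available via
  `settings$mortality_conditional`.
* **Bound anomalies.** Two input rows place the point estimate outside its
  own printed interval (CTZ/TAZ first- and second-line cure). Validation
  records and warns about these instead of rejecting or silently "fixing"
  them; the bounds are config-overridable.
* **Cohort starting age** is not part of the source input tables; 65 years
  is the default (vHABP/VABP trial populations are elderly) and it is
  configurable.
* **Hospitalization costs** are per-arm scalars (the daily tariff
  decomposition behind them is not an input); they therefore do not vary in
  the sensitivity analyses, which is worth remembering when reading the
  tornado.

## Numerical conventions

* Days convert to years at 365.25 d/yr. "One month" (ward stay, terminal
  ICU) is one model cycle, 30 days.
* Acute-phase costs and QALYs are undiscounted: at 2%/yr everything inside
  the first model year is distorted by well under 1%, and the long-term
  phase dominates the horizon.
* The cohort engine uses start-of-cycle occupancy with discounting at the
  cycle midpoint and no half-cycle correction; the horizon is hit exactly by
  a fractional final cycle. Each acute pathway enters the long-term phase at
  its own elapsed time (e.g. 28 d after cure on first line, 49 d after
  second line), so later entrants get fewer cycles; the 5-year clock starts
  at treatment, not discharge.
* The ward month is accrued **in the cohort engine** (utility, one-off 7.6%
  mortality), not in the acute tree, to avoid double counting; the
  standalone `acute_qaly()` operation keeps an `include_ward` switch for use
  outside the pipeline. Ward decedents accrue the full ward month's utility
  (the 7.6% × half-month refinement is far below other uncertainties).
* Background mortality uses integer-age life-table lookup with the annual
  probability converted to the cycle length by the constant-hazard formula
  `1 − (1 − q)^(days/365.25)`; ward mortality is per stay, applied once.
* ICU time is valued at the ventilated-ICU utility for the whole ICU stay
  (the utility source defines the state as ventilated pneumonia care in the
  ICU).

## Sensitivity analyses

**One-way (tornado).** Every parameter with finite bounds — the trial-rate
95% intervals, duration ranges, the two adverse-event cost upper bounds, the
three utilities, and the discount rate over 0–4% — is set to each bound with
everything else at base values; the output is the INMB range at the WTP,
sorted widest first, with a `crosses_zero` flag. Efficacy rates sweep
jointly with their complements through the tree; a bound that would make
`cure + mortality > 1` (MEPM first-line cure at 0.75 does) is truncated to
the feasible boundary and flagged. The sweep restores the object it was
given: the base case re-evaluates bit-identically afterwards.

**Probabilistic.** Conventional families: beta for probabilities and the two
positive utilities, gamma for durations and costs, normal for the ICU
utility (clamped to \[−1, 1\]); moment-matched with `SE = (upper − lower)/3.92`.
Parameters without printed bounds are held fixed, the discount rate too.
Draws come from one seeded generator in a canonical (sorted-path) order, so
a seed fully reproduces the analysis; infeasible efficacy draws are
truncated as in the one-way analysis (cure kept, mortality reduced). A
thousand draws evaluate in a few seconds; per draw the model records
incremental cost and QALYs, from which the CE plane, the probability each
strategy is optimal (highest NMB, ties split) and the acceptability curve
over a 0–20M yen grid (step 500,000) are computed. No correlation structure
is imposed between parameters — none is available to estimate one from.

Because the published appendix with the study's actual distribution list is
not available, these PSA specs are *reconstructions by convention*. The
base-case increments reproduce closely, but the probability-optimal figure
is sensitive to which parameters carry uncertainty: with the large
hospitalization costs necessarily fixed (no bounds exist for them), the
incremental-cost spread here is narrower than the published plane, and the
probability that CTZ/TAZ is optimal at 5M yen comes out around 0.65 rather
than the published 0.533. This is a documented reconstruction limit, not a
tunable.

## Synthetic inputs

Two inputs the analysis needs are not printed anywhere and ship as synthetic
stand-ins, clearly labelled as such:

* **Life table** (`make_life_table()`): Gompertz hazard
  `q(a) = 1 − exp(−α e^{β(a−a₀)})`, defaults α = 0.01, β = 0.09 over ages
  60–110 — about 1% annual death probability at 65 rising log-linearly, the
  order of magnitude of a high-income-country table. It is *not* official
  vital statistics; substitute a real table via the two-column CSV
  (`age,qx`) and the configuration file for substantive use. Fitting
  log cumulative hazard against age recovers (α, β) to numerical precision,
  which the tests use as a parameter-recovery oracle.
* **Trial outcomes** (`simulate_trial()`): per-arm multinomial draws over
  {cured, died, neither} with Wilson 95% intervals, emulating the structure
  (not the patients) of a two-arm trial read-out; `parameters_from_trial()`
  turns a simulated read-out into a runnable parameter set. What passing
  tests on these generators show is that the *pipeline* behaves correctly
  under realistic statistical structure — not that the synthetic inputs
  match any real population.

## Verification strategy and problem sizes

The suite checks, among others: exact fee-schedule arithmetic for every
closed-form cost component; probability conservation in the tree and in
every trace cycle (10⁻¹²); equality of the weighted cost aggregation with an
independent enumeration of all seven root-to-leaf paths (10⁻⁹ relative); the
cohort engine against a closed-form summation in the constant-hazard case
and against a 10⁵-patient individual-level microsimulation (within
Monte-Carlo error); the INMB/ICER sign identity; bitwise seed
reproducibility of the PSA; and mean-convergence of PSA increments to the
base case under symmetric (all-normal) specs at 5,000 draws with a 3×MC-SE
tolerance. Monte-Carlo sizes (10⁵ microsimulated patients, 5,000
symmetric-spec draws, 2,000 coverage replicates at n = 180) are chosen to
make the statistical tolerances sharp while keeping the full suite around
two minutes.

## Known limitations

* Susceptibility rates, resistance emergence and transmission effects are
  out of scope, as are societal-perspective costs and budget impact.
* The PSA reconstruction cannot recover the unpublished distribution list;
  see above.
* Post-discharge healthcare costs are zero by assumption.
* The model is a two-strategy comparison; no efficiency frontier over three
  or more strategies is computed.
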