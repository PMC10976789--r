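# vabpcea

Cost-effectiveness analysis of ceftolozane/tazobactam (CTZ/TAZ) versus
meropenem (MEPM) for ventilated hospital-acquired / ventilator-associated
bacterial pneumonia (vHABP/VABP) from the Japanese healthcare-payer
perspective, for health-economics analysts who want the model as inspectable,
tested code rather than a point-and-click tree.

## The model

A hybrid decision-tree + Markov cohort structure:

* **Acute phase (decision tree).** First-line therapy in the ICU ends in
  cure, death, or escalation (probability `1 − cure − mortality`) to
  second-line therapy (first-line drug + amikacin, 21 extra ICU days), which
  ends in cure, death, or long-term ICU care (one terminal month, then
  death). Cured patients are discharged directly or spend one ward month
  (7.6% per-stay mortality) first. Costs: daily drug tariffs × duration,
  per-arm hospitalization, two-tier ventilation tariff (¥9,500/day ≤ day 14,
  ¥8,150/day after), expected adverse-event treatment (incidence ×
  per-event cost), lump-sum long-term ICU/ward care.
* **Long-term phase (Markov).** Survivors move through
  {DischargedAlive, InWard, Dead} in 30-day cycles to a 5-year horizon from
  treatment start, dying at an age-indexed background rate; both phases
  accrue QALYs (annual utilities −0.39 ICU-ventilated, 0.77 ward, 0.80
  discharged) and discounting is 2%/yr.

For strategies *i* (CTZ/TAZ) vs *c* (MEPM):

    ICER  = (C_i − C_c) / (Q_i − Q_c)
    INMB  = λ (Q_i − Q_c) − (C_i − C_c),   λ = 5,000,000 yen/QALY

plus a one-way sensitivity analysis (tornado of INMB over each parameter's
bounds) and a probabilistic sensitivity analysis (moment-matched
beta/gamma/normal draws; CE plane, probability-optimal, acceptability
curve).

## Worked example

```r
library(vabpcea)

params <- reference_inputs()   # built-in reference inputs (or load_parameters("config.yaml"))
res <- evaluate_ce(params)
res
#> Cost-effectiveness results (ctz_taz vs mepm)
#>   mepm     total cost    2,497,962.56 yen   total QALYs   2.28
#>   ctz_taz  total cost    2,923,884.80 yen   total QALYs   2.44
#>   incremental cost       425,922.23 yen
#>   incremental QALYs          0.1611
#>   ICER                 2,643,684.66 yen/QALY
#>   INMB at WTP 5,000,000: 379,624.36 yen
```

CTZ/TAZ costs about ¥426k more per patient over five years (driven by a
~¥270k/course dearer drug, partly offset by its higher cure rate saving
hospital resources) and yields ~0.16 extra QALYs (more survivors reaching
the 0.8-utility discharged state), so each QALY gained costs ~¥2.64M — below
the ¥5M willingness-to-pay, hence the positive INMB.

```r
tor <- run_owsa(params)        # tornado; tor$crosses_zero flags decision flips
plot(tor)

psa <- run_psa(params, n_iter = 1000, seed = 1)
psa$p_optimal                  # probability each strategy has the higher NMB
plot(psa, type = "ceac")
```

Report bundles (CSV/JSON + manifest) via `report_base_case()`,
`report_owsa()`, `report_psa()`, `report_simulate()`, or the thin CLI at
`inst/scripts/vabpcea-cli.R`. Synthetic generators (`make_life_table()`,
`simulate_trial()`) stand in for the unpublished life table and
patient-level trial data; see the methods vignette
(`vignettes/model-methods.Rmd`) for assumptions, conventions and
limitations.

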