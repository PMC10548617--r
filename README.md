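# vomscba

Cost-benefit analysis of virtual overdose monitoring services (VOMS/MORS)
— telephone- or app-based harm-reduction hotlines, such as Canada's
National Overdose Response Service (NORS), that remotely supervise a
substance-use session and dispatch EMS or a community responder when an
overdose occurs.

Because callers are anonymous, these services cannot be evaluated by
linking records to health data. This package instead implements the full
call-log-based evaluation as a tested pipeline, for health economists and
harm-reduction program evaluators:

- **Call-log tallying** — per-period counts of overdoses, EMS call-outs
  (T_EMS), false positives (T_FC), community responses (T_CR), and unique
  overdosing callers (N).
- **Medical-systems costing** —
  `TMSc = T_EMS (c_amb + c_ED + c_MD + c_nal + p_hosp c_hosp) + T_FC c_amb + T_CR c_nal`.
- **Human-capital valuation** — value of one prevented death
  `V = income × employment rate × (retirement age − median age at death)`.
- **Counterfactual deaths averted** — `Np = N (Pn − Pi)`, with Pn the
  death probability after an unwitnessed overdose and Pi the on-service
  death probability (0 in the base case).
- **Net benefit and benefit-to-cost ratio** —
  `TCB = N Pn V − TOc − TMSc`, ratio `N Pn V / (TOc + TMSc)`.
- **Uncertainty apparatus** — Monte Carlo over Pn, exact (Garwood) Poisson
  intervals for Pi, a service-scaling grid, a two-way operating-cost ×
  mortality sensitivity grid, and the break-even mortality rate.
- **Synthetic data** — a calibrated stochastic call-log generator plus a
  deterministic fixture reproducing the published NORS service counts, so
  every stage is testable without sensitive records.

Everything is tidyverse-native: data frames in, tibbles out, with
`tidy()`, `glance()` and `autoplot()` methods on results.

## Worked example

```r
library(vomscba)

cba <- nors_fixture() |>            # bundled reference call log
  tally_calls() |>                  # per-period service counts
  cost_benefit_analysis()           # bundled nors2022 parameter profile

print(cba)
```

```
Cost-benefit analysis (nors2022 profile, Pn = 0.45, range 0.08-0.8)

 Period   N  Value of deaths averted Operating     Medical     Net benefit
 Funded 1 13 $7,723,782.38           $787,500.00   $163,290.52 $6,772,991.86
 Funded 2 10 $5,941,371.06           $580,875.00   $58,435.66  $5,302,060.40
 Total    23 $13,665,153.44          $1,368,375.00 $221,726.18 $12,075,052.26
 B:C
 8.12 (1.44-14.44)
 9.29 (1.65-16.52)
 8.59 (1.53-15.28)

Value of one life: $1,320,304.68 | break-even Pn: 0.0524
```

Reading this: across both funded periods, 23 unique callers overdosed
while monitored. At the 45% counterfactual mortality estimate, preventing
those deaths is worth $13.67M against $1.59M of program and medical costs
— a net benefit of $12.08M, or $8.59 returned per dollar spent. The range
in brackets spans the literature's 8%–80% mortality estimates, and the
program breaks even once unwitnessed-overdose mortality exceeds ~5.2%.

The uncertainty tools follow the same pattern:

```r
monte_carlo_mortality(monte_carlo_spec("uniform", 0.08, 0.80), n = 23,
                      value_of_life = 1320304.68)
poisson_exact_ci(0, 23)          # on-service mortality bound: (0, 0.160)
two_way_sensitivity(23, 1368375, 221726.18, 1320304.68) |> autoplot()
```

`run_full_cba("fixture", out_dir = "cba-report")` writes the full report
bundle (parameter echo, tally, life-years, cost-benefit, both grids, JSON
summary) as CSV/JSON/markdown; `inst/cli/vomscba` wraps the same stages as
shell subcommands (`tally`, `costs`, `benefits`, `grids`, `simulate`,
`run`).

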