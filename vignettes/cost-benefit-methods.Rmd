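---
title: "Cost-benefit methods for virtual overdose monitoring services"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cost-benefit methods for virtual overdose monitoring services}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vomscba)
```

## The problem

Virtual overdose monitoring services (VOMS/MORS) are hotlines and apps that
remotely supervise a substance-use session: a peer operator stays on the
line and, if the caller becomes unresponsive, dispatches either emergency
medical services (EMS) or a nearby community responder with naloxone. The
Canadian National Overdose Response Service (NORS) is the flagship
telephone-based example. Because callers are anonymous, service records
cannot be linked to health administrative data, so the economic case for
these services has to be built from the operator call logs plus published
unit costs and mortality estimates. This package implements that
evaluation as a reusable, tested pipeline.

`vomscba` takes a payer's perspective (federal program funding plus
provincial health-system costs), values benefits in undiscounted 2022 CAD,
and reports the primary outcomes of such an evaluation: net benefit and
the benefit-to-cost ratio.

## The model

Three quantities drive everything.

**Medical-systems cost (TMSc).** Each EMS-attended overdose triggers the
ambulance fee, an emergency-department visit, a physician assessment, one
nasal naloxone kit, and a hospital admission with probability 0.33 entering
as an expected value:

$$\mathrm{TMS_c} = T_{\mathrm{EMS}}\,(c_{\mathrm{amb}} + c_{\mathrm{ED}} +
c_{\mathrm{MD}} + c_{\mathrm{nal}} + p_{\mathrm{hosp}}\,c_{\mathrm{hosp}})
 + T_{\mathrm{FC}}\,c_{\mathrm{amb}} + T_{\mathrm{CR}}\,c_{\mathrm{nal}}$$

where $T_{\mathrm{EMS}}$, $T_{\mathrm{FC}}$ and $T_{\mathrm{CR}}$ count EMS
overdose call-outs, false-positive call-outs and community-based responses
per period. Under the bundled `nors2022` profile the per-overdose EMS
pathway costs $518 + 1061 + 196.83 + 125 + 0.33 \times 7803 = \$4{,}475.82$.
Hospitalization is an expected value, not a sampled count, because the
evaluation prices the pathway rather than simulating admissions. EMS
call-outs for non-overdose emergencies (psychosis, domestic violence) are
tallied but not priced: they are not part of the overdose pathway.

**Value of a prevented death.** The human-capital approach: average annual
income in the 35-44 age band ($73{,}530$), times the employment rate among
people who use substances (0.67), times remaining productive years
(retirement age 64.8 minus median age at drug-toxicity death 38, i.e.
26.8 years), giving $\$1{,}320{,}304.68$ per life. No discounting and no
morbidity/QALY weighting is applied — the valuation is deliberately the
simplest defensible one, which also keeps it comparable with the supervised
consumption site literature it mirrors.

**Deaths averted.** The counterfactual asks how many of the $N$ unique
individuals who overdosed on the line would have died had the overdose gone
unwitnessed: $N_p = N\,(P_n - P_i)$, where $P_n$ is the probability of
death after an unwitnessed overdose and $P_i$ the probability of death
while using the service. The base case sets $P_i = 0$ (no deaths have
occurred on any monitored session) and $P_n = 0.45$, the Monte Carlo point
estimate over the published literature range 0.08-0.80.

Net benefit is then
$T_{CB} = N\,P_n\,V - \mathrm{TO_c} - \mathrm{TMS_c}$ and the
benefit-to-cost ratio is $N\,P_n\,V / (\mathrm{TO_c} + \mathrm{TMS_c})$ —
the denominator includes both operating and medical cost.

## Key parameter choices

| parameter | default | units | why |
|---|---|---|---|
| ambulance fee | 518 (240-848) | CAD/call-out | national average across provincial fee schedules |
| ED visit | 1,061 | CAD/visit | ambulatory-classification costing for overdose |
| physician fee | 196.83 | CAD (2022) | 176 source-year dollars, inflation-adjusted; the model always consumes the inflated value |
| naloxone | 125 | CAD/kit | intranasal kit; conservative vs the $30 intramuscular kit |
| hospitalization | 7,803 x 0.33 | CAD x prob | national average admission cost, admission rate 26-40% |
| operating cost | 787,500 + 580,875 | CAD/period | per-period program budget lines |
| income, employment | 73,530, 0.67 | CAD/yr, — | age-band average; conservative employment assumption |
| $P_n$ | 0.45 (0.08-0.80) | prob | Monte Carlo point estimate; range spans a modelled 10% floor and an expert-consensus 80% ceiling |

Two bookkeeping choices deserve a note. First, the program's reported
operating total ($1,366,749) differs by $1,626 from the sum of its
per-period budget lines ($787,500 + $580,875 = $1,368,375); every published
ratio derives from the per-period lines, so those are the default and the
reported total is selectable via
`cba_profile(use_reported_operating_total = TRUE)`. Second, $N$ defaults to
*identified* unique overdose callers (13 + 10 = 23). Overdoses by callers
with no recorded identifier (4) cannot be deduplicated; including them
(`include_unknown = TRUE`, $N = 27$) is the optimistic variant.

## Numerical conventions

Currency arithmetic is done in doubles and rounded **half-up to cents**
(`round_half_up()`; base `round()` rounds half to even, which financial
tables do not) exactly once, at component sums — this reproduces the
published period costs $163,290.52 and $58,435.66 to the cent. Ratios are
kept unrounded internally and displayed to 2 decimals. Deaths averted stay
real-valued internally; integer displays round to nearest. Degenerate
inputs are flagged rather than fatal inside the pipeline: an empty call log
yields zero-valued tables with the benefit-to-cost ratio reported `NA`
(with a warning) when there is no cost base, while the standalone
`benefit_cost_ratio()` treats a zero denominator as an error.

## Uncertainty apparatus

**Monte Carlo over $P_n$.** The sampling distribution of $P_n$ is not
pinned down by the source evaluation, so `monte_carlo_spec()` exposes it:
the default is uniform(0.08, 0.80) — the literature range, with analytic
mean 0.44, consistent with the 0.45 point estimate — with 100,000 draws
and an explicit seed; triangular and fixed variants are available, and the
published tables are reproduced with the fixed 0.45 scenario. With the
fixed rate and all 66 recorded overdose events (including the unfunded
start-up months) the simulation reports a mean of 29.7, displayed as 30
deaths averted. Summaries are deterministic given `(seed, n_draws)`.

**Exact Poisson interval for $P_i$.** With zero observed deaths among 23
exposed callers, the on-service death probability is bounded with the
Garwood interval from chi-square quantiles (`poisson_exact_ci()`):
lower bound 0, upper bound $-\ln(0.025)/23 \approx 0.160$. The Garwood
form is chosen over a normal approximation because counts are tiny; the
test suite checks it against an independent tail-sum inversion oracle.

**Scaling grid.** `deaths_averted_grid()` projects
$\mathrm{round}(N (P_n - P_i))$ for services scaled to 1,000-10,000
overdosing users, with $P_i$ on a 0-0.7% grid. That $P_i$ grid is far
inside the Poisson upper bound above; it illustrates small incremental
on-service mortality rather than its confidence limit.

**Two-way sensitivity.** `two_way_sensitivity()` varies the operating
budget (40%-200% of current, medical cost held fixed — scaling only the
discretionary budget matches how the program would actually grow) against
$P_n$ over 8%-80%, reporting net benefit and ratio per cell. Net benefit
increases strictly in $P_n$ and decreases strictly in the multiplier. The
break-even mortality, `total cost / (N x value per life)`, is 0.0524: the
service pays for itself once more than ~5% of unwitnessed overdoses would
have been fatal. The published ratio range (1.53-15.28) is the pair of
ratios at $P_n = 0.08$ and $0.80$ — the arithmetic matches exactly — not a
Monte Carlo percentile interval, and that is what the package reports.

## The synthetic generator and what tests can show

`generate_call_log()` emulates the statistical structure of the service:
multinomial call categories (substance-use 0.603, mental-health 0.264,
referral 0.023, other 0.110), overdoses Bernoulli among substance-use
calls (rate 60/3113), an 11/60 community-response share, rare
false-positive (2/5159) and non-overdose-emergency (4/5159) EMS
dispatches, a ~1/15 unknown-caller rate, and caller identities drawn from
a gamma-weighted pool (concentration 0.3, pool 500) — a
Dirichlet-multinomial allocation, so call volume concentrates in few
repeat callers, mirroring the supervised-consumption-site observation that
the top 1% of clients account for ~25% of overdose events. Timestamps are
uniform within periods; no diurnal or seasonal structure is modelled
because none is reported for the service.

`nors_fixture()` is different: a deterministic, hand-constructed log whose
tally reproduces the published service counts cell for cell (5,159 calls,
60 overdoses, 49 EMS call-outs, 11 community responses, 2 false positives,
23 unique + 4 unknown overdose callers). It is synthetic — timestamps and
caller codes are invented — but it makes the whole pipeline reproducible
end to end without access to sensitive records.

Passing tests on generated data show the pipeline recovers configured
rates and preserves invariants; they cannot show that real call logs obey
the generator's simplifications (independent calls, stationary rates, no
caller linkage across periods).

## Problem sizes in the test suite

Tests use the full 5,159-record fixture, 100,000-draw Monte Carlo runs,
and 200-replicate generator-recovery checks at 1,000 calls per replicate;
the whole suite runs in a few seconds on one CPU.

## Known limitations

- Published per-period "deaths prevented" counts (21 and 7) are not
  derivable from $N = 23$ and $P_n = 0.45$ (which give 10.35); the
  life-years table therefore accepts prevented-death counts as direct
  inputs (`run_full_cba(deaths_prevented = ...)`) and reproduces the
  downstream dollar values without endorsing a derivation.
- Morbidity, ICU stays, QALYs and the unvalued benefits of mental-health
  support and referrals are out of scope, as in the source evaluation.
- The human-capital valuation is contested; it values lives by lost
  earnings and is used here for comparability, not as an ethical claim.
- No record linkage across periods: a caller active in both funded periods
  counts once per period, which is exactly how the published unique counts
  (13 + 10 = 23) are constructed.
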