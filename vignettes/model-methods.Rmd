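---
title: "Model and methods: evolocumab cost-effectiveness in the Brazilian SUS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: evolocumab cost-effectiveness in the Brazilian SUS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evocea)
```

## The decision problem

`evocea` implements a decision-analytic cost-effectiveness comparison of
two lipid-lowering strategies for secondary cardiovascular prevention in
the Brazilian public health system (SUS): high-intensity atorvastatin
(80 mg/day) alone, versus atorvastatin plus the PCSK9 inhibitor
evolocumab (140 mg every two weeks). The target population is outpatients
with coronary artery disease, a recent acute coronary syndrome, and
LDL-c of at least 70 mg/dL despite optimized statin therapy — i.e.
patients who would have been eligible for the pivotal evolocumab
outcomes trial. The health outcome is a composite of four major
cardiovascular events over a 10-year horizon: myocardial infarction
(MI), ischemic stroke, myocardial revascularization, and cardiovascular
death. Costs are taken from a societal perspective anchored on SUS
reimbursement values, in constant 2017 BRL. The headline result is the
incremental cost-effectiveness ratio (ICER), in BRL per composite
cardiovascular outcome avoided.

## Baseline risk

Each patient's 10-year composite-event risk is read off a published
table of high-risk categories for statin-treated patients (packaged as
`risk_categories()`). A patient may qualify for several categories;
`assign_category()` keeps the one with the **highest band midpoint**
(`category_midpoint()`, the arithmetic mean of the band ends), breaking
midpoint ties by table order. The cohort's baseline risk is the mean of
the per-patient midpoints; `cohort_baseline_risk()` also accepts a fixed
override, which the default configuration sets to 35% — the cohort-level
value of the reference evaluation this package encodes.

One category, "CAD with poorly controlled risk factors", has no
operational definition in the source table. We define eligibility as
current smoking: it is the one unambiguously uncontrolled modifiable
risk factor in the generated profiles, whereas hypertension and diabetes
under treatment carry their own explicit categories. This choice only
affects cohort-derived baseline risks, not the default (override)
analysis.

## Treatment effect: the LDL-to-risk translation

The treatment effect is a two-step translation:

1. **LDL-c lowering.** Adding evolocumab reduces LDL-c by an additional
   59% (`ldl_on_treatment()`), applied to the cohort mean (111 mg/dL in
   the default configuration), giving 45.51 mg/dL and a decrement
   $\Delta_{LDL} = 65.49$ mg/dL. The translation is applied at the
   cohort level, matching the reference evaluation; per-patient
   translation is possible by mapping `translate_risk()` over a cohort,
   but the default pipeline does not use it.
2. **Risk reduction per unit of LDL-c lowering.** Meta-analytic evidence
   for statins gives a 21% relative reduction in major cardiovascular
   events per 39 mg/dL of LDL-c lowering. `relative_risk_reduction()`
   scales this linearly by default,
   $RRR = 0.21 \cdot \Delta_{LDL} / 39$ (capped at 1), and rounds to the
   nearest whole percent: $0.21 \times 65.49 / 39 = 0.3526 \to 35\%$.
   The rounding ("reference" mode) is deliberate: the downstream chain
   $35\% \times (1 - 0.35) = 22.75\%$ and the absolute risk reduction of
   12.25 points are exact only under the rounded value, so the reference
   arithmetic evidently used it. A `raw` mode keeps full precision, and
   a `compounding` scaling $1 - (1-0.21)^{\Delta/39}$ is provided for
   sensitivity exploration; the two scalings agree exactly at 0 and at
   one block (39 mg/dL), with the linear form above the compounding one
   in between.

The trial effect was observed over roughly 26 months; following the
reference evaluation, the derived RRR is held constant over the 10-year
horizon. This extrapolation is an assumption, not an estimate.

## Markov cohort model

`run_trace()` iterates a five-state discrete-time cohort model: an
event-free state, three post-event states (MI, stroke,
revascularization) and absorbing cardiovascular death. Cycles are
annual and the horizon is 10 cycles — the simplest structure consistent
with a 10-year horizon. Every alive state carries the same per-cycle
composite-event hazard; an event moves the patient to the corresponding
post-event state (or death), so recurrent events are allowed and each
incident event — including a recurrence within the same state — carries
a fresh payoff. There is no background non-cardiovascular mortality.

The 10-year risk $R$ is converted to a per-cycle probability under a
constant hazard, $p = 1 - (1 - R)^{1/10}$ (`per_cycle_probability()`),
so that the probability of remaining event-free over the whole horizon
round-trips to $1 - R$ exactly.

**Payoffs.** Drug costs accrue per cycle for the alive occupancy
(treatment stops at death); event payoffs accrue on incident
transitions: the SUS hospitalization reimbursement for MI, stroke or
revascularization, or the human-capital death cost on entry to the
death state. All payoffs in cycle $t$ are discounted by
$(1+r)^{-t}$ with $r = 0.05$/year (an end-of-cycle convention; cycle 0
is the model start and carries no payoff). A half-cycle correction flag
is available for drug costs (mid-cycle discounting of the average of
start- and end-of-cycle alive occupancy) but is off by default, as the
reference evaluation gives no indication of using one.

**Effectiveness.** The default definition is the probability of never
experiencing a composite event over the horizon — the event-free
occupancy at cycle 10, undiscounted. An alternative,
discounted event-free years, is available via
`markov_spec(effectiveness = "discounted_event_free_years")`. The
reference evaluation's printed per-strategy "global effectiveness"
values (0.54 / 0.73) are not recoverable from its printed inputs under
any simple definition we tried (nor are its global costs, 46,522.44 /
236,141.85 BRL); the software it used does not report its payoff
bookkeeping. The package therefore treats those four numbers as
*replication inputs*: `default_run_config(replicate_globals = TRUE)`
carries them as overrides so the published incremental comparison
(incremental cost 189,619.41 BRL) can be reproduced and propagated,
while the model's own traces are always computed and reported alongside.

## Costing

All values are constant 2017 BRL; monetary outputs are reported to two
decimals with half-up rounding (`round_half_up()`).

* **Drugs** (`regimen_cost()`): atorvastatin 2 × 40 mg tablets/day at
  R$ 1.00 × 365 days × 10 years = R$ 7,300.00; evolocumab at R$ 901.61
  per 140 mg syringe, 24 doses/year × 10 years, giving R$ 223,686.40
  for the combined regimen. Twice-monthly dosing is encoded as exactly
  24 doses/year because that — and not 365/15 ≈ 24.33 — reproduces the
  published combined total to the centavo; a strict every-15-days mode
  (`regimen_combined(strict_interval = TRUE)`) is available.
* **Hospitalizations**: SUS reimbursements of R$ 588.12 (MI), R$ 463.21
  (stroke) and R$ 6,756.37 (revascularization) per event.
* **Premature cardiovascular death** (`premature_death_cost()`), by the
  human-capital approach: with cohort mean age 63 and death assumed on
  average at year 5 of the horizon (age 68), against a sex-adjusted life
  expectancy of 75 years 8 months, the years of life lost are
  7.667 → 7.7 (rounded to one decimal *before* monetisation — the
  convention under which 7.7 × R$ 22,128.00 = R$ 170,385.60 is exact).
  The annual income is the 2017 population mean adjusted for
  unemployment. The death cost is computed once at cohort level, not
  per patient.
* **Event mix** (`event_mix()`): the expected cost of "a composite
  event" weights the four components by their relative frequencies.
  The packaged default is externally sourced — first-event counts in
  the placebo arm of the pivotal evolocumab trial (MI 639, stroke 262,
  revascularization 965, cardiovascular death 240), normalized — since
  the reference evaluation cites those proportions without printing
  them. Its printed mean event cost (R$ 23,145.40) is under-determined
  (one equation, four unknown weights); the packaged mix yields
  R$ 22,749.10 under the default unit costs, within 1.8% of it, and the
  mix is fully configurable.

## Sensitivity analysis

**Deterministic (`one_way_dsa()`).** Each flat model parameter —
baseline risk, RRR, the three hospitalization costs, both drug prices,
annual income, discount rate — is varied one way to ±20% of its base
value holding the others fixed; the per-parameter ICER pairs, their
tornado ordering, and the overall envelope are reported. Excursions
that would leave a parameter's domain (risk above 100%, RRR above 1)
are clamped with a warning. The overall envelope necessarily brackets
the base-case ICER.

**Probabilistic (`run_psa()`).** Second-order Monte Carlo over the
cohort model: 1,000 seeded draws by default, each re-running the full
cost/effect pipeline. The uncertainty distributions are not specified
by the reference evaluation; following standard practice the defaults
are **gamma** for monetary parameters and **beta** for
probability-scale parameters (baseline risk, RRR), moment-matched to
the base value with the SD set so that ±20% of the mean spans a 95%
interval. Every distribution is overridable per parameter
(`config$psa$distributions`), including degenerate (`"fixed"`)
distributions under which the PSA reproduces the base case exactly —
a property the test suite exercises. Patient-level (first-order)
microsimulation noise is deliberately out of scope: the quantity of
interest is parameter uncertainty around cohort expectations.

**Summaries.** `summarize_psa()` reports mean, SD, median and the
2.5/10/90/97.5 percentiles of cost and effectiveness per strategy.
Percentiles use linear interpolation between closest ranks
(`stats::quantile()` type 7); the convention is pinned so summary
values are reproducible. `ceac()` computes the cost-effectiveness
acceptability curve on a willingness-to-pay grid (default 0 to 2
million BRL in 10,000-BRL steps, covering the region where the curve
crosses): at threshold $\lambda$ the combined strategy is
cost-effective in a draw when its incremental net benefit
$\lambda\,\Delta E - \Delta C$ is positive. When the combined strategy
is more effective in every draw, the curve is monotone and crosses 0.5
at the draws' median ICER.

## Synthetic cohort generator

`generate_cohort()` emulates the 61-patient outpatient sample the
reference evaluation was built on: age 63 ± 11 years truncated to the
trial's 40–85 eligibility window, 52% male, hypertension 83%, diabetes
42%, smoking 31%, prior MI 54%, no prior stroke, ezetimibe 10%, LDL-c
111 ± 34 mg/dL floored at the 70 mg/dL eligibility threshold, HDL-c
45 ± 13, triglycerides 159 ± 97. All members carry a recent acute
coronary syndrome (the cohort inclusion criterion); chronic kidney
disease, peripheral artery disease and familial hypercholesterolemia
were not reported and default to prevalence 0, configurable.

Design choices worth knowing:

* **Flags are drawn independently.** Only marginals are published; no
  correlation structure is claimed or modelled. Real comorbidities are
  correlated (diabetes–hypertension, smoking–age), so joint-prevalence
  statistics of generated cohorts should not be over-interpreted;
  marginal statistics are faithful.
* **Moment-matched truncated normals.** Sampling a normal with the
  published moments and then truncating would bias the realised mean
  (for LDL-c, to ≈118 mg/dL). The generator instead solves for the
  parent $(\mu, \sigma)$ whose *truncated* distribution has the
  published mean and SD (`fit_truncnorm()`). For LDL-c this solution is
  a diffuse parent ($\mu \approx 18$, $\sigma \approx 70$) — effectively
  a decaying tail above 70 — which reproduces mean 111 and SD 34
  exactly and implies 53.1% of patients at LDL-c ≥ 100 mg/dL,
  statistically consistent with the observed 35/61 (57%) at that sample
  size. The published strata are treated as emergent, not as hard
  constraints. Moments that no truncated normal can attain (e.g. an SD
  exceeding the floor-to-mean gap allows) raise an explicit error.
* **Determinism.** Generation is fully determined by `(spec, seed)` and
  leaves the global RNG state untouched.

Passing cohort tests therefore show that the generator reproduces the
published *marginal* structure under hard eligibility bounds — not that
it reproduces the real patients' joint distribution.

## Numerical conventions and degenerate inputs

* Monetary outputs: half-up rounding to 2 decimals; years of life lost:
  half-up to 1 decimal before monetisation.
* Transition rows must sum to 1 within 1e-12 (checked before
  iteration); occupancy rows are verified to 1e-9 in tests; the engine
  matches an exhaustive path-enumeration oracle to 1e-12 at short
  horizons.
* `icer()` refuses to divide when the effectiveness difference is 0
  (the ICER is flagged undefined) and classifies dominance.
* Category assignment: ties on midpoint break by table order; a patient
  qualifying for no category raises an error rather than a silent NA.
* Configuration: one YAML-serialisable object (`run_config()`), schema
  validated; unknown keys are rejected with their path.

Problem sizes in the shipped tests: cohorts of 61–500 for behaviour,
100,000 for convergence of marginals; PSA runs of 300–1,000 draws;
brute-force Markov oracles at 1–3 cycles. The full suite runs in well
under a minute.

## Known limitations

* The model inherits the reference evaluation's structural
  simplifications: no background mortality, a single shared event
  hazard across alive states, constant RRR over 10 years, and
  cost-only consequences of non-fatal events (no utilities — the
  effectiveness unit is "composite outcome avoided", not QALYs).
* The published per-strategy global totals and headline ICER
  (R$ 1,011,188.07) cannot be derived from published inputs; the
  package reproduces every desk-checkable intermediate exactly
  (`check_reference_values()`) and reproduces the published incremental
  comparison through replication overrides, but its own base-case ICER
  (≈ R$ 1.33M per outcome avoided under the default configuration)
  differs from the published one. Both are reported.
* PSA distributions and the DSA's exact parameter set are modelling
  choices, not published facts; conclusions about uncertainty reflect
  those choices.
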