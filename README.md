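# evocea

Cost-effectiveness of adding the PCSK9 inhibitor **evolocumab** to
high-intensity **atorvastatin** for secondary cardiovascular prevention
in the Brazilian public health system (SUS).

PCSK9 inhibitors produce large additional LDL-cholesterol reductions in
statin-treated patients, but at a retail price that dwarfs SUS
hospitalization reimbursements. For a health-system decision the
question is not whether the drug works but what it costs per event
avoided. `evocea` implements the full decision-analytic pipeline for
that question, for a secondary-prevention cohort (coronary artery
disease, recent acute coronary syndrome, LDL-c ≥ 70 mg/dL despite
optimized statins):

1. **Synthetic cohort** — seeded generator matched to the published
   61-patient sample marginals (age 63 ± 11, 52% male, LDL-c 111 ± 34
   floored at 70, ...), with moment-matched truncated normals under the
   trial eligibility bounds.
2. **Baseline risk** — each patient gets the highest-midpoint published
   10-year risk band they qualify for; the default configuration fixes
   the cohort mean at 35%.
3. **Treatment effect** — an additional 59% LDL-c reduction, translated
   at 21% relative risk reduction per 39 mg/dL of LDL-c lowering
   (linear, rounded to the whole percent):
   RRR = 0.21 × 65.49/39 → **35%**, so 35% baseline risk → **22.75%**
   treated risk (absolute risk reduction **12.25** points).
4. **Costing** (2017 BRL) — drugs (R$ 7,300.00 atorvastatin-only vs
   R$ 223,686.40 combined over 10 years), SUS hospitalization
   reimbursements per event, and the human-capital cost of premature
   cardiovascular death: 7.7 years of life lost × R$ 22,128.00/year =
   **R$ 170,385.60**.
5. **Markov cohort model** — five states (event-free, MI, stroke,
   revascularization, CV death), annual cycles over 10 years,
   constant-hazard risk-to-probability conversion
   p = 1 − (1 − R)^(1/10), 5%/year discounting.
6. **CEA** — ICER = ΔC/ΔE in BRL per composite cardiovascular outcome
   avoided, one-way ±20% deterministic sensitivity (tornado), 1,000-draw
   probabilistic sensitivity analysis, and the cost-effectiveness
   acceptability curve (CEAC).

Everything is tibble-in/tibble-out and pipe-friendly, with
`tidy()`/`glance()` methods and `autoplot()` displays for each result
type.

## Worked example

```r
library(evocea)

cfg <- default_run_config()   # published inputs, baseline risk 35%
res <- run_base_case(cfg)
res$cea
#> <cea_result> atorvastatin_evolocumab vs atorvastatin
#>   cost:             175107.15 vs     12789.64  (delta 162317.50)
#>   effectiveness:       0.7725 vs       0.6500  (delta 0.1225)
#>   ICER: 1325040.83 BRL per outcome avoided
```

Read: under the model's own bookkeeping, ten years of combined therapy
cost R$ 175,107 per patient (discounted) against R$ 12,790 for statin
monotherapy, and raise the probability of remaining free of any
composite event from 0.65 to 0.7725 — about R$ 1.33 million per
cardiovascular outcome avoided. Every desk-checkable published
intermediate is reproduced exactly:

```r
check_reference_values()
#>   quantity                            expected  computed tolerance pass
#> 1 drug_cost_standard                   7300.00   7300.00     0.005 TRUE
#> 2 drug_cost_combined                 223686.40 223686.40     0.005 TRUE
#> 3 years_of_life_lost                      7.70      7.70     0.050 TRUE
#> 4 premature_death_cost               170385.60 170385.60     0.005 TRUE
#> 5 ldl_on_treatment                       45.50     45.51     0.050 TRUE
#> 6 rrr_percent                            35.00     35.00     0.500 TRUE
#> 7 treated_risk_10y                       22.75     22.75     0.005 TRUE
#> 8 arr                                    12.25     12.25     0.005 TRUE
#> 9 incremental_cost_published_globals 189619.41 189619.41     0.005 TRUE
```

Uncertainty propagation:

```r
psa <- run_psa(cfg, n_draws = 1000, seed = 42)
summarize_psa(psa)
#>   strategy attribute        mean      sd  median    p2.5     p10     p90   p97.5
#> 1 combined cost          1.76e+5 1.72e+4 1.75e+5 1.42e+5 1.54e+5 1.97e+5 2.10e+5
#> 2 combined effectiveness 7.74e-1 2.65e-2 7.75e-1 7.20e-1 7.40e-1 8.08e-1 8.25e-1
#> 3 standard cost          1.27e+4 1.25e+3 1.27e+4 1.04e+4 1.12e+4 1.43e+4 1.53e+4
#> 4 standard effectiveness 6.52e-1 3.55e-2 6.53e-1 5.83e-1 6.04e-1 6.96e-1 7.22e-1

ceac(psa) |> dplyr::filter(wtp %in% c(0, 1e6, 1.5e6, 2e6))
#>       wtp prob_combined prob_standard
#> 1       0         0            1
#> 2 1000000         0.041        0.959
#> 3 1500000         0.724        0.276
#> 4 2000000         0.988        0.012
autoplot(ceac(psa))
```

The combined strategy only becomes the probable cost-effective choice
at a willingness to pay well above R$ 1 million per outcome avoided —
far beyond any threshold in use — so under these prices the addition of
evolocumab is not cost-effective. `one_way_dsa(cfg)` shows the ICER is
most sensitive to the baseline risk, the RRR and the evolocumab syringe
price (base-case envelope ≈ R$ 1.06M–1.67M).

The per-strategy global totals printed by the original evaluation
(R$ 46,522.44 / R$ 236,141.85 at effectiveness 0.54 / 0.73) come from
unreported internal bookkeeping and are not derivable from its printed
inputs; `default_run_config(replicate_globals = TRUE)` carries them as
replication overrides, reproducing the published incremental cost of
R$ 189,619.41 exactly. See the methods vignette
(`vignettes/model-methods.Rmd`) for the model, its assumptions and its
limitations.

A thin command-line wrapper ships at `inst/cli/evocea.R`
(`generate-cohort`, `base-case`, `dsa`, `psa`, `ceac`,
`reference-case`, with `--config/--seed/--out/--format/--verbose`).

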