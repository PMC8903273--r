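# spmscea

Cost-effectiveness and budget-impact modelling of disease-modifying therapy
(DMT) in secondary progressive multiple sclerosis (SPMS), from the Italian
NHS perspective.

The package is for health economists and HTA analysts who need a tested,
scriptable implementation of the standard EDSS-state Markov approach to SPMS
therapy appraisal: siponimod versus interferon beta-1b over a lifetime
horizon, and a three-year budget-impact model of siponimod's market entry
that also prices ocrelizumab.

## The model

**Cost-effectiveness.** A cohort Markov model over 21 states — EDSS 0–9 on
treatment, EDSS 0–9 off treatment, and death — with annual cycles from age
48 to 100. Per cycle, death competes first (life-table background mortality
weighted by the cohort sex mix, with an EDSS-specific rate ratio applied as
`q' = 1 − (1 − q)^m`), then treated patients may discontinue
(`1 − (1 − p₀)^h`), then survivors move between EDSS levels; treatment
stops on reaching EDSS 7. Treatment efficacy enters as a hazard ratio on
confirmed disability progression, applied to the natural-history matrix on
the rate scale,

```
p' = 1 − (1 − p)^HR
```

over each row's aggregate upward probability (redistributed proportionally;
improvement untouched), plus a relative risk on the annual relapse rate.
Outcomes are discounted (3%/year) costs, life-years and QALYs, summarised
as the ICER ΔC/ΔE and net monetary benefit `WTP·ΔE − ΔC` at €40,000/QALY,
with one-way (tornado) and probabilistic sensitivity analysis,
cost-effectiveness acceptability curves, and a CDP-3 alternative-endpoint
scenario.

**Budget impact.** An epidemiology funnel (59.6 M population → 5,827
siponimod-eligible patients) combined with per-year market shares for two
worlds, with and without siponimod, over three years; budgets price drug
acquisition, administration/monitoring (first-year vs later tariffs),
adverse events, and management/relapse costs.

Inputs published only in the source article's supplement — the placebo-arm
transition matrix, the baseline discontinuation probability, market shares —
are generated by a seeded synthetic-data module (`synth_config()`,
`gen_transition_matrix()`, `gen_life_table()`, `gen_market_scenarios()`)
as structurally faithful, clearly labelled stand-ins. Headline published
point values therefore reproduce qualitatively, not numerically; the
vignette discusses exactly what is and is not testable.

## Worked example

```r
library(spmscea)

params <- spms_parameters()        # published tables + seeded synthetic stand-ins
eligibility_funnel(params$funnel, params$national_population)
#>   stage               proportion    count
#> 1 national_population      1     59641488
#> 2 ms_prevalent             0.002   119283
#> 3 spms                     0.137    16342
#> 4 age18_60_edss3_6.5       0.918    15002
#> 5 active                   0.6       9001
#> 6 treated                  0.65      5851
#> 7 eligible                 0.996     5827

cea <- run_cea(params)
tidy(cea)
#>   arm                total_cost life_years qalys delta_cost delta_ly delta_qaly    icer     nmb
#> 1 interferon_beta_1b    163070.       17.3  4.18        NA       NA       NA        NA      NA
#> 2 siponimod             260823.       17.7  5.13     97753.    0.376    0.942   103743. -60063.
```

Reading the output: on the *synthetic* natural history, siponimod adds 0.94
discounted QALYs and €97.8k per patient versus interferon beta-1b, an ICER
of €103,743/QALY — above the €40,000 threshold, hence the negative net
monetary benefit. (The published analysis, using its supplement-only
transition matrix, reported ΔQALY 1.05, ΔC €30,308 and an ICER of
€28,891/QALY; the gap is driven by how long patients stay on drug under the
stand-in natural history.) The funnel, by contrast, uses only published
inputs and reproduces the published counts exactly.

Sensitivity and budget impact chain the same way:

```r
autoplot(run_owsa(params))                       # tornado on NMB
draws <- sample_psa(params, n = 5000, seed = 1)
autoplot(ceac(draws))                            # acceptability curves
run_bia(params)                                  # 3-year budget impact
```

A thin CLI wrapper ships in `inst/cli/spmscea.R`
(`run-cea | run-owsa | run-psa | run-cdp3 | run-bia | gen-synthetic`).

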