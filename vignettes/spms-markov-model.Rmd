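---
title: "An EDSS Markov cohort model for cost-effectiveness and budget impact of SPMS therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An EDSS Markov cohort model for cost-effectiveness and budget impact of SPMS therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spmscea)
library(dplyr)
```

## The decision problem

Secondary progressive multiple sclerosis (SPMS) is the phase of continuous
disability accumulation that follows relapsing-remitting MS. Disability is
measured on the Expanded Disability Status Scale (EDSS, 0 = normal to 9 =
bedridden in this model's live range; EDSS 10 is death from MS). Siponimod,
an oral sphingosine-1-phosphate receptor modulator, slows confirmed
disability progression in active SPMS; the question for a payer is whether
its benefit justifies its price against interferon beta-1b, the incumbent
therapy, and what its market entry costs the system over the first years.

`spmscea` answers both questions from the Italian NHS perspective with two
linked models:

1. a **cohort Markov model** of lifetime disability progression
   (cost-effectiveness: ICER, net monetary benefit, one-way and
   probabilistic sensitivity analysis, acceptability curves, and an
   alternative-endpoint scenario), and
2. a **budget-impact model** comparing total expenditure over three years
   between a market with and without siponimod.

## State space and cycle structure

The Markov model has 21 states: EDSS 0--9 on treatment, EDSS 0--9 off
treatment, and death. The source publication's text says "10 states: 9 for
each EDSS level and 1 corresponding to death", while its input table
parameterises ten EDSS columns (0--9); we follow the table, since every
per-state input (relapse probability, utility, mortality multiplier,
management cost) is printed for ten levels. Half-point EDSS values from the
trial population (3.0--6.5) are mapped to the integer grid by flooring, so
"EDSS `<=` 6.5" eligibility becomes "level `<=` 6".

The cohort starts at age 48.0 with 39.9% males, distributed over EDSS 2--7
(0.49 / 9.32 / 18.59 / 16.09 / 55.33 / 0.18 percent at EDSS 2..7), all on
treatment. Cycles are annual. Within a cycle events are ordered:

1. **Death** competes first. The background probability comes from the life
   table, weighted by the cohort sex mix, and the EDSS-specific mortality
   rate ratio (1.00 at EDSS 0 up to 6.45 at EDSS 9) is applied on the rate
   scale, `q' = 1 - (1 - q)^m`, capped at 1.
2. **Discontinuation**: surviving treated patients below the stopping level
   stop therapy with probability `1 - (1 - p0)^h`, where `p0` is the
   baseline annual discontinuation probability and `h` the arm's
   discontinuation hazard ratio (interferon beta-1b is the reference,
   `h = 1`; siponimod uses 0.87).
3. **EDSS movement** by the arm-adjusted matrix if on treatment, the
   natural-history matrix if off.
4. **Stopping rule**: anyone arriving at EDSS 7 or above while on treatment
   moves to the off-treatment branch. Discontinued patients revert to
   natural-history progression, keep management and relapse costs, accrue no
   drug or administration cost, and cannot restart (the source is silent on
   re-treatment; no-restart is the conservative reading of a stopping rule).

Alternative orderings (discontinuation before death, say) differ at order
`q x p` per cycle and are not identifiable from the published outputs; the
ordering above is fixed and documented rather than configurable.

The lifetime horizon is operationalised as 52 cycles (age 100) or live mass
below 1e-6, whichever comes first. There is no half-cycle correction in the
base case -- costs and effects are valued on start-of-cycle occupancy -- but
`spms_parameters(half_cycle = TRUE)` switches to trapezoidal valuation.

## Treatment effects

Relative efficacy comes from a published matching-adjusted indirect
comparison, consumed as inputs (re-estimating it is out of scope): hazard
ratios versus placebo on 6-month confirmed disability progression (CDP-6:
siponimod 0.50, interferon beta-1b 0.93) and relative risks on the
annualised relapse rate (0.59 / 0.65). The progression HR adjusts the
natural-history matrix row by row on the rate scale:

$$p' = 1 - (1 - p)^{HR},$$

where `p` is the row's aggregate probability of moving to any *higher* EDSS
level; the adjusted mass is redistributed over the higher destinations in
proportion to their original shares and the difference is absorbed by the
stay probability. Improvement probabilities are untouched. This is the
standard convention in NICE-style MS models; it preserves row-stochasticity
for any positive HR, treats the HR as acting on the progression rate rather
than the one-year probability, and makes `HR = 1` an exact no-op. The
relapse RR scales the on-treatment relapse probabilities directly.

Mortality has no direct treatment effect: therapy reduces mortality only
indirectly, by keeping patients at lower EDSS where the multiplier is
smaller. Efficacy is assumed constant while on treatment (no waning), which
may flatter the intervention over a lifetime horizon.

```{r adjust}
m <- gen_transition_matrix(synth_config(seed = 2022))
round(adjust_progression(m, 0.50)[4, ], 4) # siponimod-adjusted EDSS-3 row
```

## Economics

Outcomes are discounted life-years, QALYs (EDSS-specific utilities from
0.832 at EDSS 0 to -0.214 at EDSS 9) and costs: annual management by EDSS
band (EUR 2,102 / 4,822 / 8,052 for EDSS 0--3 / 4--6 / 7--9), EUR 405 per
relapse, drug acquisition from ex-factory pack prices on a 365.25-day year
(siponimod 2 mg/day, 28-tablet pack at EUR 1,890.9; interferon beta-1b
0.25 mg every 48 h, per-vial price EUR 57.06 -- Extavia and Betaferon differ
by under a cent per vial), and administration/monitoring tariffs split into
a first-year and a subsequent-year rate. The first-year tariff is keyed to
model time (the first cycle) rather than per-patient treatment duration; the
source does not distinguish, and the switch is `admin_year1_by`. Relapses
carry costs only, no utility decrement, because the utility table is defined
purely by EDSS. Both costs and effects discount at 3% per year; the
willingness-to-pay threshold is EUR 40,000 per QALY.

The incremental comparison reports the ICER `dC/dE` (flagged when dominance
or a zero QALY difference makes it misleading) and the net monetary benefit
`WTP x dE - dC`, an identity the test suite asserts to numerical precision.

## Sensitivity analysis

The one-way analysis moves each parameter with a printed range or CI to its
bounds and records the NMB span (tornado). The probabilistic analysis draws
all parameters independently -- the source gives no correlation structure --
with families assigned by standard CEA practice, since the source prints
only ranges: log-normal for HRs/RRs (point estimate as median, `sdlog` from
the CI width), gamma for costs, beta for probabilities and utilities, with
negative-capable utilities (EDSS 8--9) on a location-shifted support
`[-1, 1]`. Printed ranges are treated as 95% intervals, matched by moments.
Relapse probabilities have no printed range and enter the PSA with a
synthetic 20% band; mortality multipliers (printed CIs) enter the
one-way analysis only. The default replicate count is 5,000 (the source
does not state its count). Dirichlet resampling of the transition-matrix
rows is available behind `vary_transitions = TRUE` but off by default; the
source does not say whether its PSA varied the matrix.

The acceptability curve reports, per WTP value, the fraction of replicates
in which each arm has the highest NMB, ties broken toward the reference arm.
The CDP-3 scenario reruns the identical pipeline with the 3-month-endpoint
hazard ratios (siponimod 0.61, interferon beta-1b 0.74); because that pair
narrows siponimod's relative advantage (0.61/0.74 versus 0.50/0.93), its
ICER exceeds the base case's on any reasonable natural history.

## Synthetic stand-ins for unpublished inputs

Four inputs of the original analysis exist only in its supplement and are
generated here as structurally faithful stand-ins (deterministic given the
seed; packaged default seed 2022). They are **not** claimed to equal the
originals, and no attempt is made to reverse-engineer them from the printed
ICER -- so the headline point values (ICER EUR 28,891/QALY, NMB EUR 11,654,
PSA 78% at EUR 40,000, BIA +0.9%) are reproducible only qualitatively, a
limitation stated up front.

* **Natural-history transition matrix** (the trial's placebo arm): a
  band-dominant row-stochastic 10x10 matrix -- mass on stay and one-level
  moves, small two-level jumps, progression mass at least improvement mass
  at every level, no improvement from EDSS 9 -- with base progression
  probability 0.16/year, improvement 0.03/year, and a small seeded
  log-normal jitter so the band is not exact. Before the generator was
  built, an independent fundamental-matrix computation on the band skeleton
  fixed the plausibility window for the mean EDSS 3 to 7 time at
  16.7--31.1 years (point value 23.9); the test suite re-estimates it by
  microsimulation on the generated matrix and asserts it stays inside.
* **Background life table**: Gompertz hazard `a e^{b age}` over ages
  18--100, `b = 0.085`, `a` set so the sex-mix-weighted death probability at
  the cohort's starting age 48 is about 2e-3, male hazard 1.6x female. The
  sex mix is handled by weighting the two columns 39.9/60.1 each cycle
  rather than simulating sexes separately -- a cohort-level approximation.
* **Baseline discontinuation**: 0.10/year, a synthetic default with no
  published provenance, applied to both arms (siponimod through its HR
  0.87).
* **Market scenarios** for the budget model: the without-siponimod world
  continues the pre-launch trend (interferon declining 8 points/year into a
  still-growing ocrelizumab share, from year-1 shares 30/52/18
  interferon/ocrelizumab/untreated); the with-siponimod world follows a
  logistic uptake fitted through the two published patient-count anchors
  (405 treated in year 1, 2,236 in year 3, of 5,827 eligible), displacing
  interferon mainly in the first two years (5.5 and 4.5 share points) and
  ocrelizumab mainly in the third, as the source describes qualitatively.

What the synthetic data do not emulate: the real placebo matrix's level-
specific progression rates (ours are flat across levels up to jitter), any
age- or duration-dependence of progression, calendar trends in prices, and
real-world adherence. Tests passing on these inputs therefore demonstrate
the *correctness of the machinery* -- conservation, ordering, identities,
calibration anchors, oracle agreement -- not agreement with the published
point estimates.

## Budget-impact model

The eligible population comes from the published epidemiology funnel
(national population 59,641,488; proportions 0.2%, 13.7%, 91.8%, 60%, 65%,
99.6%). The funnel carries full precision down the chain and rounds only
the reported stage counts; chaining already-rounded counts would shift the
final stage by one patient. The population is held constant over the three
years (prevalent steady state).

Each scenario-year's budget is the eligible count times the share-weighted
per-patient annual cost: drug acquisition (ocrelizumab: 600 mg every six
months, costed as two printed-price vials per administration, 4 x EUR 6,250
= EUR 25,000/year), the administration/monitoring tariff with the first-year
rate applied to newly gained share (year-on-DMT approximated by share
growth), an annual adverse-event management cost (synthetic, EUR 150 for
each DMT, identical across DMTs so it cancels in the scenario difference),
plus mean management and relapse costs over the fixed baseline EDSS
distribution. Progression is not simulated: over three years the scenario
difference is dominated by drug costs, and the disease-cost block is common
to both worlds. The budget impact is the yearly and cumulative with-minus-
without difference; on the packaged calibration it is positive in years 1--2
and slightly negative in year 3, matching the published signs (+1.1%, +1.6%,
-0.14%), because by year 3 siponimod is displacing similarly priced
ocrelizumab rather than cheap interferon.

```{r bia}
run_bia(spms_parameters())
```

## Numerical choices and degenerate inputs

* Row-stochasticity is enforced to 1e-12 and cohort mass conservation to
  1e-9 at every cycle (the engine aborts on violation).
* `adjust_progression(m, 1)` and degenerate PSA distributions return their
  inputs bitwise, so "no effect" comparisons are exact, not approximate.
* The HR inverse problem (recover `h` from adjusted aggregate progression
  probabilities by least squares on `1 - (1-p)^h`) is solvable to 1e-6 with
  `optimize()`, which the tests use as a round-trip check.
* Monetary text I/O is plain-dot decimal; Italian-style strings ("1.720,5")
  are converted only under an explicit `decimal_mark = ","`, never by
  guessing.
* Ages are floored to the life table's integer grid; ages beyond the table
  abort rather than extrapolate.
* Dominance and zero-QALY-difference comparisons are flagged, not errors.

## Problem sizes

The packaged analyses use 52 annual cycles, 5,000 PSA replicates, a
200,000-walker microsimulation oracle checked at cycles 1, 5 and 20 on three
seeded configurations, and 1,000 random configurations in the conservation
property test -- sizes at which every Monte-Carlo check has comfortable
resolution for the tolerances asserted.

## Known limitations

* The synthetic natural history is a stand-in; all headline point values are
  supplement-gated (see above) and only directional/structural claims are
  tested against the publication.
* On the synthetic defaults the tornado's widest bar is the siponimod
  discontinuation hazard ratio, narrowly ahead of the CDP-6 hazard ratios;
  with the original matrix the published analysis found CDP-6 efficacy most
  influential. Which treatment-effect parameter tops the ranking is
  sensitive to the natural history; the tests assert the treatment-effect
  block dominates all other inputs.
* No societal costs, no EVPI, no treatment waning, no relapse disutility,
  no re-treatment after discontinuation, no parameter correlation in the
  PSA.
* The budget model has no patient-level churn; switching is approximated at
  the share level, and the first-year tariff attaches to net share growth.
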