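Package: spmscea
Title: Cost-Effectiveness and Budget-Impact Modelling of Disease-Modifying
    Therapy in Secondary Progressive Multiple Sclerosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A cohort Markov model of disability progression on the Expanded
    Disability Status Scale (EDSS) for secondary progressive multiple sclerosis,
    with treatment effects applied as hazard-ratio adjustments to annual
    transition probabilities. Computes discounted costs, life-years and
    quality-adjusted life-years per treatment strategy, incremental
    cost-effectiveness ratios and net monetary benefit; one-way and
    probabilistic sensitivity analysis with cost-effectiveness acceptability
    curves; and a three-year budget-impact model built on an epidemiological
    eligibility funnel and market-share scenarios. Includes a synthetic-data
    module that generates structurally faithful stand-ins for unpublished
    inputs (natural-history transition matrix, background life table, market
    shares) so the full pipeline runs end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
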