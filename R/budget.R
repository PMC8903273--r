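#' Epidemiology eligibility funnel
#'
#' Chains the published proportions down from the national population:
#' MS prevalence, SPMS share, the age-18--60 / EDSS-3--6.5 share, active
#' disease, under-treatment, and siponimod eligibility. The funnel carries
#' full precision down the chain and integerises each reported stage count by
#' the chosen rounding rule, so downstream stages do not accumulate rounding
#' error.
#'
#' @param funnel Tibble with `stage` and `proportion` (see [funnel_inputs()]).
#' @param national National population count heading the funnel.
#' @param rounding `"nearest"` (default) or `"truncate"`.
#' @return A tibble: `stage`, `proportion`, `count`, beginning with the
#'   national population.
#' @export
eligibility_funnel <- function(funnel = funnel_inputs(),
                               national = 59641488,
                               rounding = c("nearest", "truncate")) {
  rounding <- match.arg(rounding)
  rnd <- if (rounding == "nearest") function(x) round(x) else function(x) trunc(x)
  counts <- numeric(nrow(funnel))
  mass <- national
  for (i in seq_len(nrow(funnel))) {
    mass <- mass * funnel$proportion[i]
    counts[i] <- rnd(mass)
  }
  bind_rows(
    tibble(stage = "national_population", proportion = 1, count = national),
    mutate(funnel, count = counts)
  )
}

#' Per-patient annual DMT cost
#'
#' Drug acquisition plus the administration/monitoring tariff for the stated
#' treatment year plus the annual adverse-event management cost. Ocrelizumab
#' is costed at 600 mg every 6 months: two vials per administration, two
#' administrations a year at the printed ex-factory vial price. Untreated
#' patients accrue no drug, administration or adverse-event cost.
#'
#' @param dmt One of `"siponimod"`, `"interferon_beta_1b"`, `"ocrelizumab"`,
#'   `"untreated"`.
#' @param year_on_treatment `"first"` or `"later"`.
#' @param params An [spms_parameters()] object.
#' @return EUR per patient-year.
#' @export
per_patient_annual_cost <- function(dmt,
                                    year_on_treatment = c("first", "later"),
                                    params = spms_parameters()) {
  year_on_treatment <- match.arg(year_on_treatment)
  bc <- params$bia_costs
  ae <- bc$ae_cost_annual
  if (dmt == "untreated") {
    return(unname(ae[["untreated"]]))
  }
  if (dmt == "ocrelizumab") {
    o <- bc$ocrelizumab
    drug <- o$vial_price * o$vials_per_admin * o$admins_per_year
    admin <- if (year_on_treatment == "first") o$admin_year1 else o$admin_later
    return(drug + admin + unname(ae[["ocrelizumab"]]))
  }
  row <- params$arms[params$arms$arm == dmt, ]
  if (nrow(row) != 1) {
    abort(sprintf("unknown DMT '%s'", dmt), class = "spmscea_config_error")
  }
  drug <- annual_drug_cost(row$pack_price, row$pack_size, row$annual_units)
  admin <- if (year_on_treatment == "first") row$admin_year1 else row$admin_later
  drug + admin + unname(ae[[dmt]])
}

# Mean annual management + relapse cost per eligible patient, over the fixed
# baseline EDSS distribution. The budget model does not simulate
# progression: over a 3-year horizon the scenario difference is dominated by
# drug costs, and the disease-cost block is common to both scenarios.
mean_disease_cost <- function(params) {
  bd <- params$cohort$baseline_dist
  e <- params$edss
  sum(bd * e$mgmt_cost) + sum(bd * e$relapse_prob) * params$settings$relapse_cost
}

#' Run the 3-year budget-impact analysis
#'
#' Computes, per year and scenario, the total payer budget: eligible
#' population times the market-share-weighted per-patient annual DMT cost
#' (drug, administration/monitoring with the first-year tariff applied to
#' newly switched share, adverse events) plus the mean management and relapse
#' cost over the baseline EDSS distribution. The budget impact is the yearly
#' and cumulative difference between the with- and without-siponimod
#' scenarios, with the eligible population held constant.
#'
#' @param params An [spms_parameters()] object.
#' @param scenarios A scenario pair from [gen_market_scenarios()]; generated
#'   from `params$synth` by default.
#' @param eligible Eligible population; defaults to the funnel's last stage.
#' @param horizon Years (3 in the published design).
#' @return An object of class `bia_result`.
#' @export
run_bia <- function(params,
                    scenarios = NULL,
                    eligible = NULL,
                    horizon = 3) {
  eligible <- eligible %||%
    dplyr::last(eligibility_funnel(params$funnel, params$national_population)$count)
  scenarios <- scenarios %||% gen_market_scenarios(params$synth, eligible)
  yrs <- seq_len(horizon)
  check_cover <- function(tbl) {
    cov <- dplyr::count(tbl, .data$year)
    if (!all(yrs %in% cov$year)) {
      abort("scenario does not cover every model year", class = "spmscea_config_error")
    }
    bad <- tbl |>
      group_by(.data$year) |>
      summarise(s = sum(.data$share)) |>
      filter(abs(.data$s - 1) > 1e-9)
    if (nrow(bad) > 0) {
      abort("market shares must sum to 1 in every year", class = "spmscea_config_error")
    }
  }
  check_cover(scenarios$with)
  check_cover(scenarios$without)
  disease <- mean_disease_cost(params)

  scenario_budget <- function(tbl) {
    wide <- tidyr::pivot_wider(tbl, names_from = "dmt", values_from = "share")
    dmts <- setdiff(names(wide), c("scenario", "year"))
    prev <- scenarios$year0[dmts]
    vapply(yrs, function(y) {
      cur <- unlist(wide[wide$year == y, dmts])
      new <- pmax(cur - prev[dmts], 0)
      cont <- cur - new
      prev <<- cur
      per <- sum(vapply(dmts, function(d) {
        cont[[d]] * per_patient_annual_cost(d, "later", params) +
          new[[d]] * per_patient_annual_cost(d, "first", params)
      }, numeric(1)))
      eligible * (per + disease)
    }, numeric(1))
  }

  b_with <- scenario_budget(scenarios$with)
  b_without <- scenario_budget(scenarios$without)
  annual <- tibble(
    year = yrs,
    budget_with = b_with,
    budget_without = b_without,
    difference = b_with - b_without,
    percent_difference = 100 * (b_with - b_without) / b_without
  )
  structure(
    list(
      annual = annual,
      total_difference = sum(annual$difference),
      percent_difference = 100 * sum(annual$difference) / sum(annual$budget_without),
      eligible = eligible,
      scenarios = scenarios
    ),
    class = "bia_result"
  )
}

#' @export
tidy.bia_result <- function(x, ...) {
  x$annual
}

#' @export
glance.bia_result <- function(x, ...) {
  tibble(
    eligible = x$eligible,
    total_difference = x$total_difference,
    percent_difference = x$percent_difference
  )
}

#' @export
print.bia_result <- function(x, ...) {
  cat(sprintf("<bia_result> eligible population: %d\n", x$eligible))
  print(x$annual)
  cat(sprintf(
    "  total difference over %d years: EUR %s (%.2f%%)\n",
    nrow(x$annual), format(round(x$total_difference), big.mark = ","),
    x$percent_difference
  ))
  invisible(x)
}

#' Export BIA results to CSV
#'
#' @param x A `bia_result`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_bia_csv <- function(x, path) {
  readr::write_csv(tidy(x), path)
  invisible(path)
}
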