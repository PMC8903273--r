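#' Annual discount weight
#'
#' `(1 + rate)^(-cycle)`; cycle 0 is undiscounted. The base case discounts
#' costs and benefits at 3% per year.
#'
#' @param cycle Integer cycle (years since model start), vectorised.
#' @param rate Annual discount rate (>= 0).
#' @return Discount weights.
#' @export
discount_factor <- function(cycle, rate) {
  if (any(rate < 0)) {
    abort("discount rate must be non-negative", class = "spmscea_parameter_error")
  }
  if (any(cycle < 0)) {
    abort("cycle must be non-negative", class = "spmscea_parameter_error")
  }
  (1 + rate)^(-cycle)
}

#' Annual drug acquisition cost
#'
#' Packs per year are the annual units required divided by the pack size on a
#' 365.25-day year (siponimod 2 mg/day: 365.25 tablets; interferon beta-1b
#' 0.25 mg every 48 h: 182.625 vials); fractional packs are allowed. Cost is
#' packs times the ex-factory pack price.
#'
#' @param pack_price Ex-factory price per pack (EUR).
#' @param pack_size Units per pack.
#' @param annual_units Units dispensed per patient-year.
#' @return EUR per patient-year.
#' @export
annual_drug_cost <- function(pack_price, pack_size, annual_units) {
  if (any(pack_size <= 0)) {
    abort("pack size must be positive", class = "spmscea_config_error")
  }
  (annual_units / pack_size) * pack_price
}

drug_cost_for_arm <- function(arm) {
  annual_drug_cost(arm$pack_price, arm$pack_size, arm$annual_units)
}

#' Accumulate discounted outcomes over a cohort trace
#'
#' Values each model year on its start-of-cycle occupancy (no half-cycle
#' correction by default): live occupancy contributes life-years, occupancy
#' times the EDSS utility contributes QALYs, and costs sum management costs
#' over live states, expected relapses times the per-relapse cost, and -- for
#' the treated-and-eligible occupancy -- drug acquisition plus the
#' administration/monitoring tariff (year-1 tariff in the first model year,
#' the later tariff afterwards). Everything is discounted at `rate`.
#'
#' @param trace A `cohort_trace`.
#' @param params An [spms_parameters()] object.
#' @param arm An [arm_spec()]; defaults to the one attached to the trace.
#' @param rate Discount rate; defaults to the parameter set's.
#' @return One-row tibble of class `arm_result`: `arm`, `total_cost`,
#'   `life_years`, `qalys`.
#' @export
accumulate <- function(trace, params, arm = attr(trace, "arm"),
                       rate = params$settings$discount_rate) {
  n <- nrow(trace)
  if (n < 2) {
    abort("trace must contain at least one completed cycle", class = "spmscea_config_error")
  }
  val <- as_tibble(trace)[seq_len(n - 1), ] # each row = the year it opens
  if (isTRUE(params$settings$half_cycle)) {
    nxt <- as_tibble(trace)[2:n, ]
    occ_cols <- c(paste0("on_edss", 0:9), paste0("off_edss", 0:9), "dead")
    val[occ_cols] <- (val[occ_cols] + nxt[occ_cols]) / 2
  }
  on <- as.matrix(val[paste0("on_edss", 0:9)])
  off <- as.matrix(val[paste0("off_edss", 0:9)])
  live <- on + off
  e <- params$edss
  df <- discount_factor(val$cycle, rate)

  ly <- as.vector(live %*% rep(1, 10))
  qaly <- as.vector(live %*% e$utility)
  mgmt <- as.vector(live %*% e$mgmt_cost)
  relapses <- expected_relapses(val, e$relapse_prob, arm$rr_arr)
  eligible <- (0:9) < arm$stop_edss
  treated <- as.vector(on[, eligible, drop = FALSE] %*% rep(1, sum(eligible)))
  admin <- if (identical(params$settings$admin_year1_by, "model_time")) {
    ifelse(val$cycle == 0, arm$admin_year1, arm$admin_later)
  } else {
    rep(arm$admin_later, nrow(val))
  }
  cost <- mgmt + relapses * params$settings$relapse_cost +
    treated * (drug_cost_for_arm(arm) + admin)

  structure(
    tibble(
      arm = arm$name,
      total_cost = sum(df * cost),
      life_years = sum(df * ly),
      qalys = sum(df * qaly)
    ),
    class = c("arm_result", class(tibble())))
}

#' Incremental comparison of two strategies
#'
#' Differences are intervention minus reference. The ICER is the incremental
#' cost per QALY gained (flagged undefined when the QALY difference is zero,
#' and flagged dominant/dominated when the sign pattern makes the ratio
#' misleading); net monetary benefit is `wtp * dQALY - dCost`.
#'
#' @param reference,intervention One-row `arm_result` tibbles.
#' @param wtp Willingness to pay (EUR per QALY gained).
#' @return One-row tibble of class `cea_comparison`.
#' @export
compare <- function(reference, intervention, wtp = 40000) {
  dc <- intervention$total_cost - reference$total_cost
  de <- intervention$qalys - reference$qalys
  dly <- intervention$life_years - reference$life_years
  icer <- if (de == 0) NA_real_ else dc / de
  flag <- dplyr::case_when(
    de == 0 ~ "undefined",
    dc < 0 & de > 0 ~ "dominant",
    dc > 0 & de < 0 ~ "dominated",
    TRUE ~ "trade-off"
  )
  structure(
    tibble(
      reference = reference$arm,
      intervention = intervention$arm,
      delta_cost = dc,
      delta_ly = dly,
      delta_qaly = de,
      icer = icer,
      dominance = flag,
      wtp = wtp,
      nmb = wtp * de - dc
    ),
    class = c("cea_comparison", class(tibble())))
}

#' Run the full cost-effectiveness analysis
#'
#' Runs both strategies through the cohort model, accumulates discounted
#' costs, life-years and QALYs, and compares the intervention against the
#' reference arm.
#'
#' @param params An [spms_parameters()] object.
#' @param reference,intervention Arm names.
#' @param endpoint `"cdp6"` (base case) or `"cdp3"` (alternative scenario).
#' @return An object of class `cea_result` with elements `arms` (per-arm
#'   outcomes), `comparison`, and the traces.
#' @export
run_cea <- function(params,
                    reference = "interferon_beta_1b",
                    intervention = "siponimod",
                    endpoint = "cdp6") {
  tr_ref <- run_cohort(params, reference, endpoint)
  tr_int <- run_cohort(params, intervention, endpoint)
  res_ref <- accumulate(tr_ref, params)
  res_int <- accumulate(tr_int, params)
  structure(
    list(
      arms = bind_rows(res_ref, res_int),
      comparison = compare(res_ref, res_int, wtp = params$settings$wtp),
      traces = list(reference = tr_ref, intervention = tr_int),
      endpoint = endpoint
    ),
    class = "cea_result"
  )
}

#' Alternative scenario under the 3-month progression endpoint
#'
#' Re-runs the identical pipeline with the CDP-3 hazard ratios substituted
#' for the CDP-6 ones.
#'
#' @inheritParams run_cea
#' @return A `cea_result`.
#' @export
run_cdp3 <- function(params,
                     reference = "interferon_beta_1b",
                     intervention = "siponimod") {
  run_cea(params, reference, intervention, endpoint = "cdp3")
}

#' @export
tidy.cea_result <- function(x, ...) {
  cmp <- x$comparison
  arms <- x$arms
  out <- mutate(arms,
    delta_cost = c(NA_real_, cmp$delta_cost),
    delta_ly = c(NA_real_, cmp$delta_ly),
    delta_qaly = c(NA_real_, cmp$delta_qaly),
    icer = c(NA_real_, cmp$icer),
    nmb = c(NA_real_, cmp$nmb)
  )
  as_tibble(out)
}

#' @export
glance.cea_result <- function(x, ...) {
  select(as_tibble(x$comparison),
    "delta_cost", "delta_qaly", "icer", "nmb", "wtp", "dominance"
  )
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("<cea_result> (%s endpoint)\n", toupper(x$endpoint)))
  print(tidy(x))
  invisible(x)
}

#' Export CEA results to CSV
#'
#' One row per arm (cost, LY, QALY) and the incremental row (delta cost,
#' delta QALY, ICER, NMB), mirroring the published results-table layout.
#'
#' @param x A `cea_result`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_cea_csv <- function(x, path) {
  readr::write_csv(tidy(x), path)
  invisible(path)
}
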