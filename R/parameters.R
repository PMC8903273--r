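#' EDSS-level clinical, utility and cost inputs
#'
#' Per-EDSS annual relapse probabilities, all-cause mortality rate ratios
#' (EDSS 0 is the referent), utility weights and annual management costs for
#' the Italian NHS perspective, each with the published uncertainty range.
#'
#' @return A tibble with one row per EDSS level 0--9.
#' @export
edss_inputs <- function() {
  tibble(
    edss = 0:9,
    relapse_prob = c(0, 0, 0.465, 0.161, 0.218, 0.168, 0.126, 0.276, 0.276, 0.276),
    mort_mult = c(1.00, 1.43, 1.60, 1.64, 1.67, 1.84, 2.27, 3.10, 4.45, 6.45),
    mort_lo   = c(0.80, 1.14, 1.28, 1.31, 1.34, 1.47, 1.82, 2.48, 3.56, 5.16),
    mort_hi   = c(1.20, 1.72, 1.92, 1.97, 2.00, 2.21, 2.72, 3.72, 5.34, 7.74),
    utility = c(0.832, 0.791, 0.737, 0.651, 0.582, 0.501, 0.412, 0.300, -0.041, -0.214),
    util_lo = c(0.646, 0.620, 0.583, 0.520, 0.467, 0.403, 0.333, 0.243, -0.049, -0.257),
    util_hi = c(0.957, 0.920, 0.866, 0.771, 0.693, 0.598, 0.494, 0.360, -0.033, -0.174),
    mgmt_cost = c(rep(2102, 4), rep(4822, 3), rep(8052, 3)),
    mgmt_lo   = c(rep(1720, 4), rep(3946, 3), rep(6589, 3)),
    mgmt_hi   = c(rep(2543, 4), rep(5834, 3), rep(9742, 3))
  )
}

#' Treatment-strategy inputs
#'
#' Relative efficacy versus placebo from the published matching-adjusted
#' indirect comparison (hazard ratio on 6-month confirmed disability
#' progression, relative risk on the annualised relapse rate), the siponimod
#' discontinuation hazard ratio versus interferon beta-1b, ex-factory pack
#' prices, annual units dispensed and administration/monitoring tariffs.
#' The interferon beta-1b price is the Extavia per-vial ex-factory price
#' (Betaferon's per-vial price differs by under one cent).
#'
#' @return A tibble with one row per strategy; the reference arm
#'   (interferon beta-1b) first.
#' @export
arm_inputs <- function() {
  tibble(
    arm = c("interferon_beta_1b", "siponimod"),
    hr_cdp6 = c(0.93, 0.50),
    hr_cdp6_lo = c(0.71, 0.35),
    hr_cdp6_hi = c(1.20, 0.74),
    rr_arr = c(0.65, 0.59),
    rr_arr_lo = c(0.48, 0.35),
    rr_arr_hi = c(0.88, 0.99),
    hr_disc = c(1.00, 0.87),
    hr_disc_lo = c(NA_real_, 0.64),
    hr_disc_hi = c(NA_real_, 1.18),
    # 0.25 mg every 48 h -> 365.25/2 vials; 2 mg/day -> 365.25 tablets
    pack_price = c(285.3, 1890.9),
    pack_size = c(5, 28),
    annual_units = c(182.625, 365.25),
    admin_year1 = c(1137, 1272),
    admin_later = c(412, 309)
  )
}

#' Hazard ratios under the 3-month confirmed-progression endpoint
#'
#' Alternative-scenario efficacy: disability progression confirmed at 3
#' months (CDP-3) instead of 6 months, from the same indirect comparison.
#'
#' @return A tibble with one row per strategy.
#' @export
cdp3_inputs <- function() {
  tibble(
    arm = c("interferon_beta_1b", "siponimod"),
    hr_cdp3 = c(0.74, 0.61),
    hr_cdp3_lo = c(0.60, 0.32),
    hr_cdp3_hi = c(0.91, 1.16)
  )
}

#' Italian SPMS epidemiology funnel
#'
#' The published eligibility funnel from national population down to patients
#' eligible for siponimod: each stage is the previous count multiplied by a
#' proportion.
#'
#' @return A tibble with columns `stage` and `proportion`; the first row
#'   carries the national population in `count0`.
#' @export
funnel_inputs <- function() {
  tibble(
    stage = c(
      "ms_prevalent", "spms", "age18_60_edss3_6.5",
      "active", "treated", "eligible"
    ),
    proportion = c(0.002, 0.137, 0.918, 0.60, 0.65, 0.996)
  )
}

#' Budget-impact cost inputs for ocrelizumab and adverse events
#'
#' Ocrelizumab is costed as 600 mg every 6 months: two 330 mg-priced vials per
#' administration, two administrations a year (4 vials x EUR 6,250), with
#' first-year and subsequent-year administration/monitoring tariffs. The
#' per-DMT annual adverse-event management cost is a synthetic input (the
#' published figure is supplement-only) applied annually and identically
#' across the three DMTs.
#'
#' @return A named list of cost components.
#' @export
bia_cost_inputs <- function() {
  list(
    ocrelizumab = list(
      vial_price = 6250, vials_per_admin = 2, admins_per_year = 2,
      admin_year1 = 1150, admin_later = 363
    ),
    ae_cost_annual = c(
      siponimod = 150, interferon_beta_1b = 150, ocrelizumab = 150, untreated = 0
    )
  )
}

default_baseline_dist <- function() {
  setNames(
    c(0, 0, 0.49, 9.32, 18.59, 16.09, 55.33, 0.18, 0, 0) / 100,
    paste0("edss", 0:9)
  )
}

#' Assemble the full model parameter set
#'
#' Bundles every input the cost-effectiveness and budget-impact analyses
#' need: the published table inputs (EDSS-level clinical/utility/cost data,
#' treatment efficacy and prices, epidemiology funnel) plus the synthetic
#' stand-ins for unpublished inputs (natural-history transition matrix,
#' background life table, baseline discontinuation probability, market-share
#' scenarios), generated deterministically from `seed`.
#'
#' @param seed Integer seed for the synthetic components. The packaged
#'   default (2022) fixes the study conditions.
#' @param synth A [synth_config()] object; overrides `seed` if supplied.
#' @param transition Optional 10x10 natural-history transition matrix to use
#'   instead of the generated one.
#' @param life_table Optional life-table tibble (`age`, `q_female`, `q_male`).
#' @param discount_rate Annual discount rate for costs and benefits.
#' @param wtp Willingness to pay, EUR per QALY gained.
#' @param horizon Number of annual cycles (default runs age 48 to 100).
#' @param stop_edss Treatment stops on reaching this EDSS level.
#' @param half_cycle Logical; apply a half-cycle correction (default `FALSE`,
#'   start-of-cycle valuation).
#' @param admin_year1_by `"model_time"` (first model cycle gets the year-1
#'   administration tariff) or `"never"` (always the later tariff).
#' @return An object of class `spms_params`.
#' @export
spms_parameters <- function(seed = 2022,
                            synth = NULL,
                            transition = NULL,
                            life_table = NULL,
                            discount_rate = 0.03,
                            wtp = 40000,
                            horizon = 52,
                            stop_edss = 7,
                            half_cycle = FALSE,
                            admin_year1_by = c("model_time", "never")) {
  admin_year1_by <- match.arg(admin_year1_by)
  cfg <- synth %||% synth_config(seed = seed)
  p <- structure(
    list(
      cohort = list(
        start_age = 48.0,
        male_fraction = 0.399,
        baseline_dist = default_baseline_dist()
      ),
      edss = edss_inputs(),
      arms = arm_inputs(),
      cdp3 = cdp3_inputs(),
      funnel = funnel_inputs(),
      national_population = 59641488,
      bia_costs = bia_cost_inputs(),
      settings = list(
        discount_rate = discount_rate,
        wtp = wtp,
        horizon = horizon,
        stop_edss = stop_edss,
        relapse_cost = 405,
        half_cycle = half_cycle,
        admin_year1_by = admin_year1_by,
        baseline_discontinuation = cfg$baseline_discontinuation
      ),
      synth = cfg,
      transition = transition %||% gen_transition_matrix(cfg),
      life_table = life_table %||% gen_life_table(cfg)
    ),
    class = "spms_params"
  )
  validate_params(p)
}

#' Validate a model parameter set
#'
#' Checks every structural invariant the model relies on: probabilities in
#' \[0, 1\], a row-stochastic transition matrix, a baseline distribution
#' summing to one, positive hazard ratios, utilities within their ranges and
#' non-increasing in EDSS, management costs non-decreasing in EDSS band, a
#' mortality multiplier of 1 at EDSS 0 and non-decreasing multipliers, and a
#' life table monotone in age past 30. Violations abort with the offending
#' field path.
#'
#' @param p An `spms_params` object.
#' @return `p`, invisibly unchanged, for chaining.
#' @export
validate_params <- function(p) {
  fail <- function(path, msg) {
    abort(paste0("invalid parameter [", path, "]: ", msg), class = "spmscea_config_error")
  }
  bd <- p$cohort$baseline_dist
  if (abs(sum(bd) - 1) > 1e-6) fail("cohort$baseline_dist", "must sum to 100%")
  if (any(bd < 0)) fail("cohort$baseline_dist", "negative share")
  if (p$cohort$male_fraction < 0 || p$cohort$male_fraction > 1) {
    fail("cohort$male_fraction", "must be a proportion")
  }
  e <- p$edss
  if (any(e$relapse_prob < 0 | e$relapse_prob > 1)) {
    fail("edss$relapse_prob", "probability outside [0,1]")
  }
  if (e$mort_mult[1] != 1) fail("edss$mort_mult", "EDSS 0 multiplier must be 1.00")
  if (any(diff(e$mort_mult) < 0)) fail("edss$mort_mult", "must be non-decreasing in EDSS")
  if (any(e$utility < e$util_lo - 1e-9 | e$utility > e$util_hi + 1e-9)) {
    fail("edss$utility", "outside printed range")
  }
  if (any(e$utility > 1)) fail("edss$utility", "utility above 1")
  if (any(diff(e$utility) > 0)) fail("edss$utility", "must be non-increasing in EDSS")
  if (any(diff(e$mgmt_cost) < 0)) fail("edss$mgmt_cost", "must be non-decreasing in EDSS")
  if (any(e$mgmt_cost < 0)) fail("edss$mgmt_cost", "negative cost")
  a <- p$arms
  if (any(a$hr_cdp6 <= 0)) fail("arms$hr_cdp6", "hazard ratio must be positive")
  if (any(a$rr_arr <= 0)) fail("arms$rr_arr", "relative risk must be positive")
  if (any(a$pack_size <= 0)) fail("arms$pack_size", "pack size must be positive")
  if (any(a$pack_price < 0)) fail("arms$pack_price", "negative price")
  s <- p$settings
  if (s$discount_rate < 0) fail("settings$discount_rate", "negative rate")
  if (s$baseline_discontinuation < 0 || s$baseline_discontinuation >= 1) {
    fail("settings$baseline_discontinuation", "must be in [0, 1)")
  }
  if (s$horizon < 1) fail("settings$horizon", "horizon must be at least 1 year")
  validate_transition_matrix(p$transition)
  lt <- p$life_table
  if (any(lt$q_female < 0 | lt$q_female > 1 | lt$q_male < 0 | lt$q_male > 1)) {
    fail("life_table", "probability outside [0,1]")
  }
  older <- lt$age > 30
  if (any(diff(lt$q_female[older]) < 0) || any(diff(lt$q_male[older]) < 0)) {
    fail("life_table", "death probability must be non-decreasing in age past 30")
  }
  fz <- p$funnel
  if (any(fz$proportion < 0 | fz$proportion > 1)) fail("funnel$proportion", "outside [0,1]")
  invisible(p)
}

#' @export
print.spms_params <- function(x, ...) {
  cat("<spms_params>\n")
  cat(sprintf(
    "  cohort: start age %.1f, male %.1f%%, baseline EDSS 2-7\n",
    x$cohort$start_age, 100 * x$cohort$male_fraction
  ))
  cat(sprintf(
    "  settings: discount %.1f%%, WTP EUR %s/QALY, horizon %d cycles, stop at EDSS %d\n",
    100 * x$settings$discount_rate, format(x$settings$wtp, big.mark = ","),
    x$settings$horizon, x$settings$stop_edss
  ))
  cat(sprintf("  synthetic seed: %d\n", x$synth$seed))
  invisible(x)
}
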