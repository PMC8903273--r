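#' Extract one treatment strategy's specification
#'
#' Pulls one arm's efficacy, discontinuation and cost inputs out of a
#' parameter set, optionally swapping in the 3-month confirmed-progression
#' hazard ratios for the alternative scenario.
#'
#' @param params An [spms_parameters()] object.
#' @param arm Arm name, e.g. `"siponimod"` or `"interferon_beta_1b"`.
#' @param endpoint `"cdp6"` (base case) or `"cdp3"` (alternative scenario).
#' @return A list of class `arm_spec`.
#' @export
arm_spec <- function(params, arm, endpoint = c("cdp6", "cdp3")) {
  endpoint <- match.arg(endpoint)
  row <- params$arms[params$arms$arm == arm, ]
  if (nrow(row) != 1) {
    abort(sprintf("unknown arm '%s'", arm), class = "spmscea_config_error")
  }
  hr <- if (endpoint == "cdp3") {
    params$cdp3$hr_cdp3[params$cdp3$arm == arm]
  } else {
    row$hr_cdp6
  }
  structure(
    list(
      name = arm,
      hr_cdp6 = hr,
      rr_arr = row$rr_arr,
      hr_disc = row$hr_disc,
      baseline_discontinuation = params$settings$baseline_discontinuation,
      stop_edss = params$settings$stop_edss,
      pack_price = row$pack_price,
      pack_size = row$pack_size,
      annual_units = row$annual_units,
      admin_year1 = row$admin_year1,
      admin_later = row$admin_later
    ),
    class = "arm_spec"
  )
}

# State layout used throughout the engine:
#   1..10  on-treatment, EDSS 0..9
#   11..20 off-treatment, EDSS 0..9
#   21     dead (absorbing)
state_names <- function() {
  c(paste0("on_edss", 0:9), paste0("off_edss", 0:9), "dead")
}

# Core operator assembly from precomputed pieces; kept free of tibble
# overhead because the PSA calls it hundreds of thousands of times.
assemble_operator <- function(adjusted, natural, qvec, disc_prob, stop_edss) {
  surv <- 1 - qvec
  O <- matrix(0, 21, 21, dimnames = list(state_names(), state_names()))
  eligible <- (0:9) < stop_edss
  # on-treatment rows, treatment-eligible levels: stay on unless the move
  # lands at or beyond the stopping level, or the patient discontinues first
  Aon <- (1 - disc_prob) * adjusted
  keep_on <- Aon
  keep_on[, !eligible] <- 0
  to_off <- Aon - keep_on + disc_prob * natural
  O[1:10, 1:10] <- surv * keep_on
  O[1:10, 11:20] <- surv * to_off
  if (any(!eligible)) {
    # on-treatment rows at/above the stop level: treatment has already
    # stopped, so they move by natural history straight into the off branch
    ne <- which(!eligible)
    O[ne, 1:10] <- 0
    O[ne, 11:20] <- surv[ne] * natural[ne, , drop = FALSE]
  }
  O[11:20, 11:20] <- surv * natural
  O[1:20, 21] <- rep(qvec, 2)
  O[21, 21] <- 1
  O
}

#' Build the full one-cycle transition operator
#'
#' Assembles the 21-state annual operator (10 EDSS levels x on/off treatment,
#' plus death) for one cycle at a given age. The event ordering within a
#' cycle is fixed: (1) death competes first, using the sex-mix-weighted
#' background probability raised on the rate scale by the EDSS mortality
#' multiplier; (2) surviving treated patients below the stopping level
#' discontinue with probability `1 - (1 - baseline)^hr_disc`; (3) survivors
#' move between EDSS levels -- by the arm-adjusted matrix if still on
#' treatment, by natural history otherwise; (4) anyone arriving at or above
#' the stopping EDSS level while on treatment is moved to the off-treatment
#' branch. Rows sum to 1 exactly up to floating point.
#'
#' @param arm An [arm_spec()].
#' @param natural The natural-history (placebo) transition matrix.
#' @param params An [spms_parameters()] object (life table, multipliers, sex mix).
#' @param age Age in years at the start of the cycle.
#' @param adjusted Optional precomputed arm-adjusted matrix (performance).
#' @return A 21x21 row-stochastic matrix.
#' @export
build_cycle_operator <- function(arm, natural, params, age, adjusted = NULL) {
  validate_transition_matrix(natural)
  adjusted <- adjusted %||% adjust_progression(natural, arm$hr_cdp6)
  qvec <- death_probability(
    age, params$cohort$male_fraction, 0:9,
    params$life_table, params$edss$mort_mult
  )
  d <- 1 - (1 - arm$baseline_discontinuation)^arm$hr_disc
  assemble_operator(adjusted, natural, qvec, d, arm$stop_edss)
}

#' Run the cohort through the Markov model
#'
#' Starts the cohort at the baseline EDSS distribution (all on treatment),
#' age 48.0 with 39.9% males under the default inputs, and iterates the
#' one-cycle operator with age advancing one year per cycle. Stops at the
#' horizon (default: 52 cycles, age 100) or when live mass falls below 1e-6.
#'
#' @param params An [spms_parameters()] object.
#' @param arm Arm name or an [arm_spec()].
#' @param endpoint `"cdp6"` or `"cdp3"`.
#' @return A `cohort_trace`: a tibble with one row per cycle (columns
#'   `cycle`, `age`, the 20 live-state occupancies and `dead`), carrying the
#'   arm spec as an attribute.
#' @export
run_cohort <- function(params, arm = "siponimod", endpoint = "cdp6") {
  if (is.character(arm)) arm <- arm_spec(params, arm, endpoint)
  bd <- params$cohort$baseline_dist
  if (abs(sum(bd) - 1) > 1e-6) {
    abort("baseline distribution must sum to 100%", class = "spmscea_config_error")
  }
  horizon <- params$settings$horizon
  natural <- params$transition
  adjusted <- adjust_progression(natural, arm$hr_cdp6)
  d <- 1 - (1 - arm$baseline_discontinuation)^arm$hr_disc

  state <- c(bd, rep(0, 10), 0) # baseline cohort sits on the on-treatment branch
  states <- matrix(NA_real_, nrow = horizon + 1, ncol = 21,
    dimnames = list(NULL, state_names())
  )
  states[1, ] <- state
  age0 <- params$cohort$start_age
  n_done <- 0L
  for (t in seq_len(horizon)) {
    qvec <- death_probability(
      age0 + (t - 1), params$cohort$male_fraction, 0:9,
      params$life_table, params$edss$mort_mult
    )
    O <- assemble_operator(adjusted, natural, qvec, d, arm$stop_edss)
    state <- as.vector(state %*% O)
    if (abs(sum(state) - 1) > 1e-9) {
      abort("mass conservation violated in cohort run", class = "spmscea_internal_error")
    }
    states[t + 1, ] <- state
    n_done <- t
    if (sum(state[1:20]) < 1e-6) break
  }
  states <- states[seq_len(n_done + 1), , drop = FALSE]
  out <- as_tibble(states)
  out <- mutate(out,
    cycle = dplyr::row_number() - 1L,
    age = age0 + .data$cycle, .before = 1
  )
  structure(out,
    class = c("cohort_trace", class(out)),
    arm = arm, endpoint = endpoint
  )
}

#' Expected relapses per cycle
#'
#' Population-fraction-weighted relapse count: for each cycle, the sum over
#' live states of occupancy times the EDSS-specific annual relapse
#' probability, with the arm's relapse-rate relative risk applied to the
#' on-treatment branch only.
#'
#' @param trace A `cohort_trace` (or any tibble with the occupancy columns).
#' @param relapse_probs Length-10 vector of annual relapse probabilities by EDSS.
#' @param arm_rr Relative risk on the annualised relapse rate while treated.
#' @return Numeric vector, one expected relapse count per trace row.
#' @export
expected_relapses <- function(trace, relapse_probs, arm_rr) {
  stopifnot(length(relapse_probs) == 10)
  on <- as.matrix(trace[paste0("on_edss", 0:9)])
  off <- as.matrix(trace[paste0("off_edss", 0:9)])
  as.vector(on %*% (relapse_probs * arm_rr) + off %*% relapse_probs)
}

#' @export
tidy.cohort_trace <- function(x, ...) {
  long <- tidyr::pivot_longer(as_tibble(x),
    cols = -c("cycle", "age"),
    names_to = "state", values_to = "occupancy"
  )
  long <- mutate(long,
    branch = dplyr::case_when(
      .data$state == "dead" ~ "dead",
      startsWith(.data$state, "on_") ~ "on_treatment",
      TRUE ~ "off_treatment"
    ),
    edss = dplyr::if_else(.data$state == "dead", NA_integer_,
      as.integer(sub(".*edss", "", sub("^dead$", "-1", .data$state)))
    )
  )
  select(long, "cycle", "age", "branch", "edss", "occupancy")
}

#' Export a cohort trace to CSV
#'
#' One row per cycle, columns for every state occupancy plus age.
#'
#' @param trace A `cohort_trace`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  readr::write_csv(as_tibble(trace), path)
  invisible(path)
}
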