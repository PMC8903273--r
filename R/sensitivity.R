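#' Parameter distribution table for sensitivity analysis
#'
#' One row per uncertain parameter: the base value, the published range or
#' 95% CI as bounds, and the distribution family used in the probabilistic
#' analysis. Families follow standard cost-effectiveness practice (the source
#' tables print only ranges, not families): log-normal for hazard ratios and
#' relative risks with `sdlog = (log(high) - log(low)) / (2 * 1.96)`, gamma
#' for costs, beta for utilities and probabilities (utilities that can go
#' negative use a beta on a support shifted to \[-1, 1\]), moments matched to
#' the base value and a normal-approximation SD `(high - low)/3.92`.
#' Relapse probabilities have no printed range; they enter the probabilistic
#' analysis with a synthetic +/-20% band (`in_owsa = FALSE`). Mortality
#' multipliers have printed CIs and enter the one-way analysis only.
#'
#' @param params An [spms_parameters()] object.
#' @return A tibble: `name`, `kind`, `base`, `low`, `high`, `in_owsa`, `in_psa`.
#' @export
param_distributions <- function(params) {
  a <- params$arms
  e <- params$edss
  rows <- list(
    tibble(
      name = paste0("hr_cdp6_", a$arm), kind = "lognormal",
      base = a$hr_cdp6, low = a$hr_cdp6_lo, high = a$hr_cdp6_hi,
      in_owsa = TRUE, in_psa = TRUE
    ),
    tibble(
      name = paste0("rr_arr_", a$arm), kind = "lognormal",
      base = a$rr_arr, low = a$rr_arr_lo, high = a$rr_arr_hi,
      in_owsa = TRUE, in_psa = TRUE
    ),
    tibble(
      name = "hr_disc_siponimod", kind = "lognormal",
      base = a$hr_disc[a$arm == "siponimod"],
      low = a$hr_disc_lo[a$arm == "siponimod"],
      high = a$hr_disc_hi[a$arm == "siponimod"],
      in_owsa = TRUE, in_psa = TRUE
    ),
    tibble(
      name = paste0("utility_edss", 0:9), kind = "beta_shifted",
      base = e$utility, low = e$util_lo, high = e$util_hi,
      in_owsa = TRUE, in_psa = TRUE
    ),
    tibble(
      name = c("mgmt_cost_edss0_3", "mgmt_cost_edss4_6", "mgmt_cost_edss7_9"),
      kind = "gamma",
      base = e$mgmt_cost[c(1, 5, 8)],
      low = e$mgmt_lo[c(1, 5, 8)],
      high = e$mgmt_hi[c(1, 5, 8)],
      in_owsa = TRUE, in_psa = TRUE
    ),
    tibble(
      name = paste0("mort_mult_edss", 1:9), kind = "lognormal",
      base = e$mort_mult[-1], low = e$mort_lo[-1], high = e$mort_hi[-1],
      in_owsa = TRUE, in_psa = FALSE
    ),
    {
      nz <- which(e$relapse_prob > 0) - 1
      tibble(
        name = paste0("relapse_prob_edss", nz), kind = "beta",
        base = e$relapse_prob[nz + 1],
        low = 0.8 * e$relapse_prob[nz + 1],
        high = pmin(1, 1.2 * e$relapse_prob[nz + 1]),
        in_owsa = FALSE, in_psa = TRUE
      )
    }
  )
  bind_rows(rows)
}

# Write one named parameter value back into a parameter set. No structural
# revalidation: sensitivity bounds may legitimately break cross-parameter
# monotonicity (e.g. one utility moved to its high bound).
set_param <- function(params, name, value) {
  set_arm <- function(col, arm) {
    params$arms[[col]][params$arms$arm == arm] <<- value
  }
  if (grepl("^hr_cdp6_", name)) {
    set_arm("hr_cdp6", sub("^hr_cdp6_", "", name))
  } else if (grepl("^rr_arr_", name)) {
    set_arm("rr_arr", sub("^rr_arr_", "", name))
  } else if (grepl("^hr_disc_", name)) {
    set_arm("hr_disc", sub("^hr_disc_", "", name))
  } else if (grepl("^utility_edss", name)) {
    k <- as.integer(sub("^utility_edss", "", name))
    params$edss$utility[k + 1] <- value
  } else if (name == "mgmt_cost_edss0_3") {
    params$edss$mgmt_cost[1:4] <- value
  } else if (name == "mgmt_cost_edss4_6") {
    params$edss$mgmt_cost[5:7] <- value
  } else if (name == "mgmt_cost_edss7_9") {
    params$edss$mgmt_cost[8:10] <- value
  } else if (grepl("^mort_mult_edss", name)) {
    k <- as.integer(sub("^mort_mult_edss", "", name))
    params$edss$mort_mult[k + 1] <- value
  } else if (grepl("^relapse_prob_edss", name)) {
    k <- as.integer(sub("^relapse_prob_edss", "", name))
    params$edss$relapse_prob[k + 1] <- value
  } else {
    abort(sprintf("unknown parameter '%s'", name), class = "spmscea_config_error")
  }
  params
}

# n random draws from one distribution row; degenerate rows return the base
# value exactly so a degenerate PSA reproduces the deterministic case bitwise.
draw_param <- function(row, n) {
  if (is.na(row$low) || is.na(row$high) || row$low == row$high) {
    return(rep(row$base, n))
  }
  switch(row$kind,
    lognormal = {
      sdlog <- (log(row$high) - log(row$low)) / (2 * 1.96)
      rlnorm(n, meanlog = log(row$base), sdlog = sdlog)
    },
    gamma = {
      s <- (row$high - row$low) / 3.92
      shape <- (row$base / s)^2
      rgamma(n, shape = shape, rate = shape / row$base)
    },
    beta = {
      s <- (row$high - row$low) / 3.92
      m <- row$base
      nu <- m * (1 - m) / s^2 - 1
      if (nu <= 0) abort(
        sprintf("beta parameterisation infeasible for '%s'", row$name),
        class = "spmscea_config_error"
      )
      rbeta(n, m * nu, (1 - m) * nu)
    },
    beta_shifted = {
      # support [-1, 1]: x = 2*z - 1 with z ~ beta
      m <- (row$base + 1) / 2
      s <- (row$high - row$low) / 3.92 / 2
      nu <- m * (1 - m) / s^2 - 1
      if (nu <= 0) abort(
        sprintf("beta parameterisation infeasible for '%s'", row$name),
        class = "spmscea_config_error"
      )
      2 * rbeta(n, m * nu, (1 - m) * nu) - 1
    },
    abort(sprintf("unknown distribution kind '%s'", row$kind),
      class = "spmscea_config_error"
    )
  )
}

#' One-way sensitivity analysis (tornado) on net monetary benefit
#'
#' Sets each parameter in turn to its low and then high bound with all others
#' at base, reruns the full cost-effectiveness analysis, and records the net
#' monetary benefit at each bound. Entries come back sorted by bar span, so
#' the first row is the most influential parameter. The base-case NMB is the
#' deterministic pipeline's own output (same code path, hence identical).
#'
#' @param params An [spms_parameters()] object.
#' @param distributions A [param_distributions()] tibble (rows with
#'   `in_owsa = TRUE` are used).
#' @param wtp Willingness to pay; defaults to the parameter set's.
#' @return A tibble of class `owsa_result` (`parameter`, `low`, `high`,
#'   `nmb_low`, `nmb_high`, `span`), with the base-case NMB as attribute
#'   `nmb_base`.
#' @export
run_owsa <- function(params, distributions = param_distributions(params),
                     wtp = params$settings$wtp) {
  params$settings$wtp <- wtp
  base_nmb <- glance(run_cea(params))$nmb
  d <- filter(distributions, .data$in_owsa)
  nmb_at <- function(name, value) {
    glance(run_cea(set_param(params, name, value)))$nmb
  }
  out <- purrr::pmap_dfr(
    list(d$name, d$base, d$low, d$high),
    function(name, base, low, high) {
      tibble(
        parameter = name, base = base, low = low, high = high,
        nmb_low = if (low == base) base_nmb else nmb_at(name, low),
        nmb_high = if (high == base) base_nmb else nmb_at(name, high)
      )
    }
  )
  out <- arrange(mutate(out, span = abs(.data$nmb_high - .data$nmb_low)),
    desc(.data$span)
  )
  structure(out,
    class = c("owsa_result", class(tibble())),
    nmb_base = base_nmb, wtp = wtp
  )
}

#' Probabilistic sensitivity analysis
#'
#' Draws every uncertain parameter independently from its distribution,
#' reruns the full model per replicate, and records incremental cost and
#' incremental QALYs. Deterministic given `seed`. Optionally the
#' natural-history transition matrix is varied as well, each row drawn from a
#' Dirichlet centred on the base row (`dirichlet_precision` pseudo-counts).
#'
#' @param params An [spms_parameters()] object.
#' @param n Number of replicates (the packaged default analysis uses 5,000).
#' @param seed Integer seed.
#' @param distributions A [param_distributions()] tibble (rows with
#'   `in_psa = TRUE` are used).
#' @param vary_transitions Logical; also resample the transition matrix.
#' @param dirichlet_precision Pseudo-count concentration for row resampling.
#' @return A tibble of class `psa_result`: `replicate`, `delta_cost`,
#'   `delta_qaly`, plus one `par_*` column per sampled parameter.
#' @export
sample_psa <- function(params, n = 5000, seed = 1,
                       distributions = param_distributions(params),
                       vary_transitions = FALSE,
                       dirichlet_precision = 100) {
  if (n < 1) abort("n must be at least 1", class = "spmscea_config_error")
  d <- filter(distributions, .data$in_psa)
  with_local_seed(seed, {
    draws <- lapply(seq_len(nrow(d)), function(i) draw_param(d[i, ], n))
    names(draws) <- d$name
    base_matrix <- params$transition
    res <- purrr::map_dfr(seq_len(n), function(r) {
      p <- params
      for (nm in names(draws)) p <- set_param(p, nm, draws[[nm]][r])
      if (vary_transitions) {
        p$transition <- dirichlet_resample(base_matrix, dirichlet_precision)
      }
      g <- glance(run_cea(p))
      tibble(replicate = r, delta_cost = g$delta_cost, delta_qaly = g$delta_qaly)
    })
    pars <- as_tibble(draws)
    names(pars) <- paste0("par_", names(pars))
    structure(dplyr::bind_cols(res, pars),
      class = c("psa_result", class(tibble())),
      seed = seed, wtp = params$settings$wtp
    )
  })
}

dirichlet_resample <- function(m, precision) {
  out <- m
  for (i in seq_len(nrow(m))) {
    pos <- m[i, ] > 0
    g <- rgamma(sum(pos), shape = m[i, pos] * precision)
    out[i, pos] <- g / sum(g)
  }
  out
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA replicates in which
#' each strategy has the highest net monetary benefit. Ties go to the
#' reference arm. Probabilities sum to 1 across arms at every WTP.
#'
#' @param draws A `psa_result`.
#' @param wtp_grid WTP grid in EUR/QALY (default 0 to 100,000 by 1,000).
#' @return A tibble of class `ceac_result`: `wtp`, `arm`, `probability`.
#' @export
ceac <- function(draws, wtp_grid = seq(0, 100000, by = 1000)) {
  if (length(wtp_grid) == 0) {
    abort("wtp_grid must be non-empty", class = "spmscea_config_error")
  }
  if (nrow(draws) == 0) {
    abort("draws must be non-empty", class = "spmscea_config_error")
  }
  probs <- vapply(wtp_grid, function(w) {
    mean(w * draws$delta_qaly - draws$delta_cost > 0) # tie -> reference
  }, numeric(1))
  structure(
    tibble(
      wtp = rep(wtp_grid, 2),
      arm = rep(c("siponimod", "interferon_beta_1b"), each = length(wtp_grid)),
      probability = c(probs, 1 - probs)
    ),
    class = c("ceac_result", class(tibble())))
}

#' Probability the intervention is cost-effective at one threshold
#'
#' @param draws A `psa_result`.
#' @param wtp Willingness to pay.
#' @return A single probability.
#' @export
prob_cost_effective <- function(draws, wtp = 40000) {
  mean(wtp * draws$delta_qaly - draws$delta_cost > 0)
}

#' @export
glance.psa_result <- function(x, ...) {
  tibble(
    n = nrow(x),
    mean_delta_cost = mean(x$delta_cost),
    mean_delta_qaly = mean(x$delta_qaly),
    prob_ce_wtp = prob_cost_effective(x, attr(x, "wtp")),
    wtp = attr(x, "wtp"),
    seed = attr(x, "seed")
  )
}
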