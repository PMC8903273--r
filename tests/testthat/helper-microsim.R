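# Individual-level microsimulation oracle: walkers move through the same
# one-cycle operators as the cohort expectation, so cohort occupancy must
# match walker fractions within Monte-Carlo error. Implemented by exact
# multinomial propagation of walker counts (equivalent to simulating each
# walker independently).
microsim_occupancy <- function(params, arm_name, n_walkers, seed,
                               cycles = c(1, 5, 20)) {
  arm <- spmscea::arm_spec(params, arm_name)
  natural <- params$transition
  adjusted <- spmscea::adjust_progression(natural, arm$hr_cdp6)
  state0 <- c(params$cohort$baseline_dist, rep(0, 10), 0)
  out <- list()
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  counts <- as.vector(rmultinom(1, n_walkers, state0))
  for (t in seq_len(max(cycles))) {
    O <- spmscea::build_cycle_operator(
      arm, natural, params,
      age = params$cohort$start_age + (t - 1), adjusted = adjusted
    )
    nxt <- numeric(21)
    for (s in which(counts > 0)) {
      nxt <- nxt + as.vector(rmultinom(1, counts[s], O[s, ]))
    }
    counts <- nxt
    if (t %in% cycles) out[[as.character(t)]] <- counts / n_walkers
  }
  out
}

# Largest |cohort - walkers| scaled by the binomial SE of the walker
# fraction (with a small floor so empty states do not divide by zero).
max_z_score <- function(trace, micro, n_walkers, cycles = c(1, 5, 20)) {
  occ_cols <- c(paste0("on_edss", 0:9), paste0("off_edss", 0:9), "dead")
  z <- 0
  for (t in cycles) {
    expected <- as.numeric(trace[trace$cycle == t, occ_cols])
    observed <- micro[[as.character(t)]]
    se <- sqrt(pmax(expected * (1 - expected), 1e-12) / n_walkers)
    z <- max(z, abs(observed - expected) / se)
  }
  z
}
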