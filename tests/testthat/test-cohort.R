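test_that("a neutral arm reduces the operator to natural history plus mortality", {
  p <- default_params()
  p$edss$mort_mult <- rep(1, 10)
  p$settings$baseline_discontinuation <- 0
  arm <- arm_spec(p, "siponimod")
  arm$hr_cdp6 <- 1
  arm$baseline_discontinuation <- 0
  O <- build_cycle_operator(arm, p$transition, p, age = 48)
  q <- death_probability(48, p$cohort$male_fraction, 0:9, p$life_table, p$edss$mort_mult)
  # marginal EDSS destination (on + off branch) is the natural matrix
  # scaled by survival; the death column carries the background probability
  marginal <- O[1:10, 1:10] + O[1:10, 11:20]
  expect_equal(marginal, unname((1 - q) * p$transition), tolerance = 1e-15,
    ignore_attr = TRUE
  )
  expect_equal(unname(O[1:20, 21]), rep(q, 2), tolerance = 1e-15)
})

test_that("certain discontinuation empties the on-treatment branch in one cycle", {
  p <- default_params()
  p$settings$baseline_discontinuation <- 1 - 1e-12 # probability ~1
  tr <- run_cohort(p, "interferon_beta_1b")
  on_mass <- rowSums(tr[2, paste0("on_edss", 0:9)])
  expect_lt(on_mass, 1e-9)
})

test_that("cycle operators are row-stochastic for random configurations", {
  for (seed in 1:25) {
    cfg <- synth_config(seed = seed)
    p <- spms_parameters(synth = cfg)
    arm <- arm_spec(p, sample(c("siponimod", "interferon_beta_1b"), 1))
    O <- build_cycle_operator(arm, p$transition, p, age = sample(48:90, 1))
    expect_true(all(abs(rowSums(O) - 1) < 1e-12))
    expect_true(all(O >= 0))
  }
})

test_that("horizon 1 yields exactly baseline plus one step", {
  p <- default_params(horizon = 1)
  tr <- run_cohort(p, "siponimod")
  expect_identical(nrow(tr), 2L)
  expect_identical(tr$cycle, 0:1)
  expect_error(spms_parameters(horizon = 0), class = "spmscea_config_error")
})

test_that("zero mortality with an identity matrix is a fixed point", {
  p <- default_params(
    transition = structure(diag(10),
      dimnames = list(paste0("edss", 0:9), paste0("edss", 0:9))
    ),
    life_table = flat_life_table(0),
    horizon = 10
  )
  p$settings$baseline_discontinuation <- 0
  tr <- run_cohort(p, "siponimod")
  on <- as.matrix(tr[paste0("on_edss", 0:9)])
  off <- as.matrix(tr[paste0("off_edss", 0:9)])
  live <- on + off
  for (t in 2:nrow(tr)) expect_equal(live[t, ], live[1, ], tolerance = 1e-15)
  expect_true(all(tr$dead == 0))
})

test_that("mass is conserved and death is absorbing along the trace", {
  p <- default_params()
  for (arm in c("siponimod", "interferon_beta_1b")) {
    tr <- run_cohort(p, arm)
    total <- rowSums(tr[, setdiff(names(tr), c("cycle", "age"))])
    expect_true(all(abs(total - 1) < 1e-9))
    expect_true(all(diff(tr$dead) >= -1e-15))
  }
})

test_that("baseline occupancy matches the published cohort distribution", {
  p <- default_params()
  tr <- run_cohort(p, "siponimod")
  expect_equal(
    as.numeric(tr[1, paste0("on_edss", 0:9)]),
    c(0, 0, 0.49, 9.32, 18.59, 16.09, 55.33, 0.18, 0, 0) / 100,
    tolerance = 1e-15
  )
  expect_true(all(tr[1, paste0("off_edss", 0:9)] == 0))
})

test_that("stronger progression efficacy never worsens EDSS or survival", {
  p <- default_params()
  arm_weak <- arm_spec(p, "siponimod")
  arm_weak$hr_cdp6 <- 0.93
  arm_strong <- arm_spec(p, "siponimod")
  arm_strong$hr_cdp6 <- 0.5
  tr_w <- run_cohort(p, arm_weak)
  tr_s <- run_cohort(p, arm_strong)
  mean_edss <- function(tr) {
    live <- as.matrix(tr[paste0("on_edss", 0:9)]) + as.matrix(tr[paste0("off_edss", 0:9)])
    as.vector(live %*% (0:9)) / pmax(rowSums(live), 1e-300)
  }
  n <- min(nrow(tr_w), nrow(tr_s))
  expect_true(all(mean_edss(tr_s)[1:n] <= mean_edss(tr_w)[1:n] + 1e-12))
  # indirect survival effect: less progression -> lower EDSS -> less mortality
  expect_true(all(tr_s$dead[1:n] <= tr_w$dead[1:n] + 1e-12))
})

test_that("identical effect sizes give bitwise identical traces", {
  p <- default_params()
  a1 <- arm_spec(p, "siponimod")
  a2 <- arm_spec(p, "interferon_beta_1b")
  a2$hr_cdp6 <- a1$hr_cdp6
  a2$rr_arr <- a1$rr_arr
  a2$hr_disc <- a1$hr_disc
  tr1 <- run_cohort(p, a1)
  tr2 <- run_cohort(p, a2)
  cols <- setdiff(names(tr1), c("cycle", "age"))
  expect_identical(as.matrix(tr1[cols]), as.matrix(tr2[cols]))
})

test_that("expected relapses weight occupancy by EDSS and treatment status", {
  p <- default_params()
  rp <- p$edss$relapse_prob
  tr <- blank_trace(1)
  tr$off_edss3 <- 1
  expect_equal(expected_relapses(tr, rp, 1), 0.161, tolerance = 1e-12)
  tr2 <- blank_trace(1)
  tr2$on_edss3 <- 1
  expect_equal(expected_relapses(tr2, rp, 0), 0)
  # half on treatment at EDSS 3 under the relapse RR, half off at EDSS 6
  tr3 <- blank_trace(1)
  tr3$on_edss3 <- 0.5
  tr3$off_edss6 <- 0.5
  expect_equal(
    expected_relapses(tr3, rp, 0.59),
    0.5 * 0.161 * 0.59 + 0.5 * 0.126,
    tolerance = 1e-12
  )
})

test_that("traces tidy to long format and export to CSV", {
  p <- default_params(horizon = 5)
  tr <- run_cohort(p, "siponimod")
  long <- tidy(tr)
  expect_identical(nrow(long), nrow(tr) * 21L)
  expect_true(all(c("cycle", "age", "branch", "edss", "occupancy") %in% names(long)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, f)
  expect_true(file.exists(f))
  back <- readr::read_csv(f, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(tr))
})
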