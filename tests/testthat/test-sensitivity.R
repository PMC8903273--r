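test_that("distribution table covers the published ranges with sane families", {
  p <- default_params()
  d <- param_distributions(p)
  expect_true(all(d$base >= pmin(d$low, d$high) & d$base <= pmax(d$low, d$high)))
  expect_true(all(d$kind[grepl("^hr_|^rr_", d$name)] == "lognormal"))
  expect_true(all(d$kind[grepl("^mgmt_cost", d$name)] == "gamma"))
  # utilities that can go negative use the shifted-support beta
  expect_true(all(d$kind[d$name %in% c("utility_edss8", "utility_edss9")] == "beta_shifted"))
})

test_that("lognormal effect draws keep the point estimate as their median", {
  p <- default_params()
  d <- param_distributions(p)
  row <- d[d$name == "hr_cdp6_siponimod", ]
  draws <- spmscea:::with_local_seed(11, spmscea:::draw_param(row, 100000))
  expect_gt(median(draws), 0.48)
  expect_lt(median(draws), 0.52)
})

test_that("a zero-width parameter yields a zero-width tornado bar", {
  p <- default_params(horizon = 20)
  d <- param_distributions(p)
  d <- d[d$name == "hr_cdp6_siponimod", ]
  d$low <- d$base
  d$high <- d$base
  ow <- run_owsa(p, d)
  expect_identical(ow$nmb_low, ow$nmb_high)
  expect_identical(ow$nmb_low, attr(ow, "nmb_base"))
})

test_that("the tornado centre equals the deterministic NMB bitwise", {
  p <- default_params()
  d <- param_distributions(p)
  ow <- run_owsa(p, d[d$name %in% c("hr_cdp6_siponimod", "utility_edss6"), ])
  expect_identical(attr(ow, "nmb_base"), glance(run_cea(p))$nmb)
  expect_true(all(diff(ow$span) <= 0)) # sorted, widest first
})

test_that("a treatment-effect parameter dominates the tornado on defaults", {
  p <- default_params()
  ow <- run_owsa(p)
  effect_pars <- c(
    "hr_cdp6_siponimod", "hr_cdp6_interferon_beta_1b",
    "rr_arr_siponimod", "rr_arr_interferon_beta_1b", "hr_disc_siponimod"
  )
  expect_true(ow$parameter[1] %in% effect_pars)
  # and the progression hazard ratios rank above every non-treatment input
  non_effect_spans <- ow$span[!ow$parameter %in% effect_pars]
  cdp6_spans <- ow$span[grepl("^hr_cdp6", ow$parameter)]
  expect_true(all(cdp6_spans > max(non_effect_spans)))
})

test_that("unknown parameter names are rejected", {
  p <- default_params()
  expect_error(spmscea:::set_param(p, "not_a_parameter", 1),
    class = "spmscea_config_error"
  )
})

test_that("PSA is reproducible and degenerates to the base case", {
  p <- default_params(horizon = 20)
  a <- sample_psa(p, n = 5, seed = 42)
  b <- sample_psa(p, n = 5, seed = 42)
  expect_identical(as.data.frame(a), as.data.frame(b))
  d <- param_distributions(p)
  d$low <- d$base
  d$high <- d$base
  one <- sample_psa(p, n = 1, seed = 1, distributions = d)
  g <- glance(run_cea(p))
  expect_identical(one$delta_cost, g$delta_cost)
  expect_identical(one$delta_qaly, g$delta_qaly)
})

test_that("PSA means approach the base case as distributions tighten", {
  p <- default_params(horizon = 20)
  d <- param_distributions(p)
  shrink <- function(f) {
    d2 <- d
    d2$low <- d$base + f * (d$low - d$base)
    d2$high <- d$base + f * (d$high - d$base)
    d2
  }
  g <- glance(run_cea(p))
  wide <- sample_psa(p, n = 40, seed = 3, distributions = shrink(0.5))
  tight <- sample_psa(p, n = 40, seed = 3, distributions = shrink(0.01))
  err <- function(x) abs(mean(x$delta_qaly) - g$delta_qaly)
  expect_lt(err(tight), err(wide))
  expect_lt(err(tight), 0.01)
})

test_that("CEAC probabilities sum to one and honour hand-computable cases", {
  mk_draws <- function(dc, dq) {
    structure(
      tibble::tibble(
        replicate = seq_along(dc),
        delta_cost = dc, delta_qaly = dq
      ),
      class = c("psa_result", class(tibble::tibble())), wtp = 40000, seed = 1
    )
  }
  # one replicate favouring each arm at WTP 40k -> 0.5 / 0.5
  d <- mk_draws(c(10000, 50000), c(1, 1))
  cc <- ceac(d, wtp_grid = 40000)
  expect_equal(sort(cc$probability), c(0.5, 0.5))
  # WTP = 0: mass goes to the cheaper arm per replicate
  cc0 <- ceac(mk_draws(c(100, 100), c(5, 5)), wtp_grid = 0)
  expect_equal(cc0$probability[cc0$arm == "interferon_beta_1b"], 1)
  # dominant intervention in every replicate -> probability 1 everywhere
  ccd <- ceac(mk_draws(c(-1, -1), c(1, 1)), wtp_grid = c(0, 40000, 100000))
  expect_true(all(ccd$probability[ccd$arm == "siponimod"] == 1))
  # sums to one across arms at every WTP
  grid <- seq(0, 100000, 10000)
  ccs <- ceac(mk_draws(c(10, -5, 20), c(0.1, -0.2, 0.5)), wtp_grid = grid)
  sums <- tapply(ccs$probability, ccs$wtp, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_true(all(ccs$probability >= 0 & ccs$probability <= 1))
  expect_error(ceac(d, wtp_grid = numeric(0)), class = "spmscea_config_error")
})

test_that("the CDP-3 scenario swaps endpoints through the same pipeline", {
  p <- default_params(horizon = 25)
  # substituting identical hazard ratios reproduces the base case
  p_same <- p
  p_same$cdp3$hr_cdp3 <- p$arms$hr_cdp6
  expect_identical(glance(run_cdp3(p_same)), glance(run_cea(p)))
  # the CDP-3 effect pair narrows siponimod's relative advantage
  base <- glance(run_cea(p))
  alt <- glance(run_cdp3(p))
  expect_gt(alt$icer, base$icer)
})

test_that("sensitivity plots build without error", {
  p <- default_params(horizon = 15)
  d <- param_distributions(p)
  ow <- run_owsa(p, d[1:3, ])
  ps <- sample_psa(p, n = 4, seed = 2)
  cc <- ceac(ps, wtp_grid = seq(0, 50000, 25000))
  expect_s3_class(autoplot(ow), "ggplot")
  expect_s3_class(autoplot(cc), "ggplot")
  expect_s3_class(autoplot(run_cohort(p, "siponimod")), "ggplot")
})
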