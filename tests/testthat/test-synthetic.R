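test_that("generated matrices are band-dominant and row-stochastic", {
  for (seed in 1:1000) {
    m <- gen_transition_matrix(synth_config(seed = seed))
    expect_true(all(abs(rowSums(m) - 1) < 1e-12))
  }
  m <- gen_transition_matrix(synth_config(seed = 2022))
  for (i in 1:10) {
    lev <- i - 1
    near <- intersect(c(i - 1, i, i + 1), 1:10)
    expect_gt(sum(m[i, near]), sum(m[i, -near])) # mass concentrated on stay/+-1
    up <- sum(m[i, seq_len(10) > i])
    dn <- sum(m[i, seq_len(10) < i])
    expect_gte(up + 1e-12, dn) # progression at least improvement
  }
  expect_identical(m[10, 10], 1) # EDSS 9: no improvement, no progression
})

test_that("zero improvement gives an upper-triangular-plus-diagonal matrix", {
  m <- gen_transition_matrix(synth_config(seed = 4, improvement_intensity = 0))
  expect_true(all(m[lower.tri(m)] == 0))
})

test_that("excess off-diagonal mass is a config error", {
  cfg <- synth_config(
    seed = 1, progression_intensity = 0.95,
    improvement_intensity = 0.3, jump2_fraction = 0.5
  )
  expect_error(gen_transition_matrix(cfg), class = "spmscea_config_error")
})

test_that("natural-history time from EDSS 3 to EDSS 7 is plausible", {
  # window pre-registered from an independent fundamental-matrix computation
  # on the band skeleton: mean 23.9 y, accepted range [16.7, 31.1] y
  m <- gen_transition_matrix(synth_config(seed = 2022))
  n <- 20000
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(99)
  m_abs <- m
  m_abs[8:10, ] <- 0
  m_abs[cbind(8:10, 8:10)] <- 1 # EDSS >= 7 absorbing
  counts <- numeric(10)
  counts[4] <- n # everyone at EDSS 3
  t_sum <- 0
  for (t in 1:600) {
    before <- sum(counts[8:10])
    nxt <- numeric(10)
    for (s in which(counts > 0)) {
      nxt <- nxt + as.vector(rmultinom(1, counts[s], m_abs[s, ]))
    }
    counts <- nxt
    newly <- sum(counts[8:10]) - before
    t_sum <- t_sum + t * newly
    if (sum(counts[8:10]) == n) break
  }
  mean_time <- t_sum / n
  expect_gt(mean_time, 16.72)
  expect_lt(mean_time, 31.05)
})

test_that("the life table is Gompertz in age with male excess", {
  lt <- gen_life_table(synth_config(seed = 1))
  expect_identical(range(lt$age), c(18L, 100L))
  expect_true(all(diff(lt$q_female) > 0))
  expect_true(all(lt$q_male > lt$q_female))
  # hazard ratio across 40 years equals exp(40 b) in closed form
  b <- synth_config()$gompertz_b
  h <- function(q) -log(1 - q)
  expect_equal(
    h(lt$q_female[lt$age == 88]) / h(lt$q_female[lt$age == 48]),
    exp(40 * b),
    tolerance = 1e-12
  )
  # sex-mix-weighted death probability at the cohort's starting age ~ 2e-3
  q48 <- 0.399 * lt$q_male[lt$age == 48] + 0.601 * lt$q_female[lt$age == 48]
  expect_equal(q48, 2e-3, tolerance = 0.01)
  flat <- gen_life_table(synth_config(seed = 1, gompertz_b = 0))
  expect_identical(length(unique(flat$q_female)), 1L)
  expect_error(synth_config(gompertz_a = 0), class = "spmscea_config_error")
  expect_error(synth_config(gompertz_b = -0.1), class = "spmscea_config_error")
})

test_that("market scenarios are calibrated to the published uptake anchors", {
  sc <- gen_market_scenarios(synth_config(), eligible = 5827)
  sipo <- sc$with[sc$with$dmt == "siponimod", ]
  expect_identical(round(sipo$share[sipo$year == 1] * 5827), 405)
  expect_identical(round(sipo$share[sipo$year == 3] * 5827), 2236)
  for (tbl in list(sc$with, sc$without)) {
    sums <- tapply(tbl$share, tbl$year, sum)
    expect_true(all(abs(sums - 1) < 1e-9))
    expect_true(all(tbl$share >= 0))
  }
  expect_true(all(sc$without$share[sc$without$dmt == "siponimod"] == 0))
  # interferon is displaced early, ocrelizumab late
  disp <- function(dmt) {
    sc$without$share[sc$without$dmt == dmt] - sc$with$share[sc$with$dmt == dmt]
  }
  expect_gt(disp("interferon_beta_1b")[1], disp("interferon_beta_1b")[3])
  expect_gt(disp("ocrelizumab")[3], disp("ocrelizumab")[1])
})

test_that("zero uptake collapses the two scenarios", {
  sc <- gen_market_scenarios(synth_config(uptake_rate = 0), eligible = 5827)
  expect_equal(sc$with$share, sc$without$share, tolerance = 1e-15)
  p <- default_params()
  bia <- run_bia(p, scenarios = sc)
  expect_true(all(abs(bia$annual$difference) < 1e-9))
})

test_that("infeasible calibration and bad inputs are config errors", {
  expect_error(gen_market_scenarios(synth_config(), eligible = 0),
    class = "spmscea_config_error"
  )
  cfg <- synth_config(ocr_share_y1 = 0.05, ifn_share_y1 = 0.77, market_trend = 0)
  expect_error(gen_market_scenarios(cfg, eligible = 5827),
    class = "spmscea_config_error"
  )
})

test_that("generated inputs satisfy every downstream invariant", {
  for (seed in c(1, 77, 31415)) {
    expect_s3_class(spms_parameters(seed = seed), "spms_params")
  }
})

test_that("a known hazard ratio is recoverable from the adjusted matrix", {
  m <- gen_transition_matrix(synth_config(seed = 8))
  for (h_true in c(0.5, 0.87, 1.3)) {
    adj <- adjust_progression(m, h_true)
    up <- function(x) vapply(1:9, function(i) sum(x[i, (i + 1):10]), numeric(1))
    p0 <- up(m)
    p1 <- up(adj)
    sse <- function(h) sum((p1 - (1 - (1 - p0)^h))^2)
    h_hat <- optimize(sse, c(0.01, 5), tol = 1e-10)$minimum
    expect_equal(h_hat, h_true, tolerance = 1e-6)
  }
})

test_that("the generated input bundle is byte-identical across runs", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- gen_input_bundle(d1, synth_config(seed = 6))
  p2 <- gen_input_bundle(d2, synth_config(seed = 6))
  for (k in c("matrix", "life_table", "scenarios")) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]))
  }
})
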