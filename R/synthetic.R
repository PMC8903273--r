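#' Configuration for the synthetic input generator
#'
#' Collects every knob of the synthetic stand-ins for inputs the published
#' analysis took from its supplement: the natural-history EDSS transition
#' matrix, the background life table, the baseline annual treatment
#' discontinuation probability, and the two market-share scenarios of the
#' budget-impact model. All generation is deterministic given `seed`.
#'
#' @param seed Integer RNG seed.
#' @param progression_intensity Base annual probability of a +1 EDSS move.
#' @param improvement_intensity Base annual probability of a -1 EDSS move.
#' @param progression_gradient Multiplicative trend of the progression
#'   probability across EDSS levels (1 = flat).
#' @param jump2_fraction Two-level moves as a fraction of one-level moves.
#' @param jitter_sd Log-normal jitter applied to off-diagonal masses so the
#'   matrix is not exactly banded; small so band dominance is preserved.
#' @param gompertz_a,gompertz_b Gompertz background-mortality hazard
#'   `h(age) = a * exp(b * age)` (female); defaults give a sex-mix-weighted
#'   annual death probability of about 2e-3 at age 48.
#' @param male_hazard_scale Male hazard as a multiple of the female hazard.
#' @param baseline_discontinuation Annual probability that a treated patient
#'   stops therapy, before any arm-specific hazard ratio. Synthetic default
#'   0.10/year (no published value).
#' @param uptake_rate Scales the calibrated siponimod uptake curve; 0 makes
#'   the two budget scenarios identical.
#' @param ifn_share_y1,ocr_share_y1,untreated_share Year-1 market shares in
#'   the world without siponimod.
#' @param market_trend Annual share shift from interferon to ocrelizumab in
#'   the without-siponimod world (ocrelizumab uptake was still growing).
#' @param ifn_displacement Share of the treated population that siponimod
#'   takes from interferon in years 1..3; the remainder of the siponimod
#'   share displaces ocrelizumab, so interferon is displaced mainly in the
#'   first two years and ocrelizumab mainly in the third.
#' @param sipo_anchor_y1,sipo_anchor_y3 Calibration anchors: siponimod-treated
#'   patient counts in years 1 and 3 at the reference eligible population.
#' @param eligible_ref Reference eligible population the anchors refer to.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 2022,
                         progression_intensity = 0.16,
                         improvement_intensity = 0.03,
                         progression_gradient = 1.0,
                         jump2_fraction = 0.15,
                         jitter_sd = 0.05,
                         gompertz_a = 2.731e-5,
                         gompertz_b = 0.085,
                         male_hazard_scale = 1.6,
                         baseline_discontinuation = 0.10,
                         uptake_rate = 1,
                         ifn_share_y1 = 0.30,
                         ocr_share_y1 = 0.52,
                         untreated_share = 0.18,
                         market_trend = 0.08,
                         ifn_displacement = c(0.055, 0.045, 0),
                         sipo_anchor_y1 = 405,
                         sipo_anchor_y3 = 2236,
                         eligible_ref = 5827) {
  cfg <- structure(as.list(environment()), class = "synth_config")
  probs <- c(
    progression_intensity, improvement_intensity,
    baseline_discontinuation, untreated_share, ifn_share_y1, ocr_share_y1
  )
  if (any(probs < 0) || any(probs > 1)) {
    abort("synth_config: probabilities must lie in [0, 1]",
      class = "spmscea_config_error"
    )
  }
  if (gompertz_a <= 0 || gompertz_b < 0) {
    abort("synth_config: gompertz_a must be positive and gompertz_b non-negative",
      class = "spmscea_config_error"
    )
  }
  cfg
}

# Evaluate `expr` under a private RNG stream; the caller's RNG state is
# untouched.
with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic natural-history EDSS transition matrix
#'
#' Builds a band-dominant, row-stochastic 10x10 annual transition matrix over
#' EDSS 0--9: probability mass concentrated on staying and on one-level moves,
#' small two-level jumps, progression mass at least the improvement mass at
#' every level, and no improvement from EDSS 9. A small seeded log-normal
#' jitter perturbs the off-diagonal masses so the matrix is not exactly
#' banded. This is a structurally faithful stand-in for the placebo-arm
#' matrix of the pivotal trial, which is published only in a supplement; it
#' is not claimed to equal it.
#'
#' @param cfg A [synth_config()].
#' @return A 10x10 matrix with dimnames `edss0`..`edss9`, rows summing to 1.
#' @export
gen_transition_matrix <- function(cfg = synth_config()) {
  p <- cfg$progression_intensity
  q <- cfg$improvement_intensity
  g <- cfg$progression_gradient
  j2 <- cfg$jump2_fraction
  with_local_seed(cfg$seed + 11L, {
    M <- matrix(0, 10, 10, dimnames = list(paste0("edss", 0:9), paste0("edss", 0:9)))
    for (i in 1:10) {
      lev <- i - 1
      up1 <- if (lev <= 8) p * g^lev else 0
      up2 <- if (lev <= 7) j2 * p * g^lev else 0
      dn1 <- if (lev >= 1 && lev <= 8) q else 0 # EDSS 9: no improvement
      dn2 <- if (lev >= 2 && lev <= 8) 0.1 * q else 0
      mass <- c(up1, up2, dn1, dn2)
      jit <- exp(rnorm(4, mean = 0, sd = cfg$jitter_sd))
      mass <- mass * jit
      if (sum(mass) > 1) {
        abort(sprintf("gen_transition_matrix: off-diagonal mass exceeds 1 in row %d", i),
          class = "spmscea_config_error"
        )
      }
      if (mass[1] + mass[2] < mass[3] + mass[4] && lev <= 8) {
        # keep progression >= improvement even under jitter
        mass[3:4] <- mass[3:4] * (mass[1] + mass[2]) / (mass[3] + mass[4])
      }
      if (mass[1] > 0) M[i, i + 1] <- mass[1]
      if (mass[2] > 0) M[i, i + 2] <- mass[2]
      if (mass[3] > 0) M[i, i - 1] <- mass[3]
      if (mass[4] > 0) M[i, i - 2] <- mass[4]
      M[i, i] <- 1 - sum(M[i, ])
    }
    M
  })
}

#' Generate a synthetic background life table
#'
#' Annual all-cause death probabilities by age (18--100) and sex from a
#' Gompertz hazard `h(age) = a * exp(b * age)`, with the male hazard scaled
#' above the female one. A stand-in for the national life table the published
#' model used (year and source unstated there).
#'
#' @param cfg A [synth_config()].
#' @return A tibble with columns `age`, `q_female`, `q_male`.
#' @export
gen_life_table <- function(cfg = synth_config()) {
  age <- 18:100
  h <- cfg$gompertz_a * exp(cfg$gompertz_b * age)
  tibble(
    age = age,
    q_female = pmin(1, 1 - exp(-h)),
    q_male = pmin(1, 1 - exp(-cfg$male_hazard_scale * h))
  )
}

logit <- function(x) log(x / (1 - x))
invlogit <- function(x) 1 / (1 + exp(-x))

#' Generate the with- and without-siponimod market scenarios
#'
#' Builds per-year (1--3) market shares over \{siponimod, interferon beta-1b,
#' ocrelizumab, untreated\} for the two budget-impact worlds. The
#' without-siponimod world continues the pre-launch trend: interferon share
#' declining, ocrelizumab growing, untreated flat. In the with-siponimod
#' world the siponimod share follows a logistic uptake fitted through the two
#' published patient-count anchors (405 in year 1, 2,236 in year 3, at 5,827
#' eligible patients), displacing interferon mainly in the first two years
#' and ocrelizumab mainly in the third. The exact shares the published
#' analysis used are supplement-only; these are calibrated synthetic
#' stand-ins.
#'
#' @param cfg A [synth_config()].
#' @param eligible Eligible patient count (> 0).
#' @return A list with tibbles `with` and `without` (columns `scenario`,
#'   `year`, `dmt`, `share`), `year0` pre-launch shares, and `eligible`.
#' @export
gen_market_scenarios <- function(cfg = synth_config(), eligible = 5827) {
  if (eligible <= 0) {
    abort("gen_market_scenarios: eligible must be positive", class = "spmscea_config_error")
  }
  s1 <- cfg$sipo_anchor_y1 / cfg$eligible_ref
  s3 <- cfg$sipo_anchor_y3 / cfg$eligible_ref
  # logistic through the two anchors; year 2 interpolated on the logit scale
  l1 <- logit(s1)
  l3 <- logit(s3)
  s <- invlogit(c(l1, (l1 + l3) / 2, l3)) * cfg$uptake_rate
  ifn0 <- cfg$ifn_share_y1
  ocr0 <- cfg$ocr_share_y1
  unt <- cfg$untreated_share
  yrs <- 1:3
  ifn_no <- ifn0 - cfg$market_trend * (yrs - 1)
  ocr_no <- ocr0 + cfg$market_trend * (yrs - 1)
  if (any(ifn_no < 0) || any(ocr_no < 0)) {
    abort("gen_market_scenarios: market trend drives a share negative",
      class = "spmscea_config_error"
    )
  }
  d_ifn <- pmin(cfg$ifn_displacement * cfg$uptake_rate, s, ifn_no)
  d_ocr <- s - d_ifn
  if (any(d_ocr > ocr_no + 1e-12)) {
    abort("gen_market_scenarios: calibration infeasible, siponimod share exceeds displaceable share",
      class = "spmscea_config_error"
    )
  }
  year0 <- c(
    siponimod = 0, interferon_beta_1b = ifn0 + cfg$market_trend,
    ocrelizumab = ocr0 - cfg$market_trend, untreated = unt
  )
  mk <- function(label, sipo, ifn, ocr) {
    tibble(
      scenario = label,
      year = rep(yrs, each = 4),
      dmt = rep(c("siponimod", "interferon_beta_1b", "ocrelizumab", "untreated"), 3),
      share = as.vector(rbind(sipo, ifn, ocr, rep(unt, 3)))
    )
  }
  list(
    with = mk("with_siponimod", s, ifn_no - d_ifn, ocr_no - d_ocr),
    without = mk("without_siponimod", rep(0, 3), ifn_no, ocr_no),
    year0 = year0,
    eligible = eligible
  )
}

#' Write the full synthetic input bundle to a directory
#'
#' Writes the generated transition matrix (CSV), life table (CSV) and market
#' scenarios (YAML) plus a small manifest. Byte-identical across runs with
#' the same configuration.
#'
#' @param dir Output directory (created if missing).
#' @param cfg A [synth_config()].
#' @return Invisibly, the paths written.
#' @export
gen_input_bundle <- function(dir, cfg = synth_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    matrix = file.path(dir, "transition_matrix.csv"),
    life_table = file.path(dir, "life_table.csv"),
    scenarios = file.path(dir, "market_scenarios.yaml"),
    manifest = file.path(dir, "manifest.json")
  )
  write_transition_csv(gen_transition_matrix(cfg), paths[["matrix"]])
  readr::write_csv(gen_life_table(cfg), paths[["life_table"]])
  sc <- gen_market_scenarios(cfg)
  yaml::write_yaml(
    list(
      eligible = sc$eligible,
      year0 = as.list(sc$year0),
      with_siponimod = scenario_to_list(sc$with),
      without_siponimod = scenario_to_list(sc$without)
    ),
    paths[["scenarios"]]
  )
  jsonlite::write_json(
    list(seed = cfg$seed, package_version = as.character(utils::packageVersion("spmscea"))),
    paths[["manifest"]],
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(paths)
}

scenario_to_list <- function(tbl) {
  out <- lapply(split(tbl, tbl$year), function(d) as.list(setNames(d$share, d$dmt)))
  names(out) <- paste0("year", names(out))
  out
}
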