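#' Serialise a parameter set to YAML
#'
#' Writes the complete, self-contained input bundle (cohort, EDSS table,
#' arms, settings, funnel, budget costs, synthetic configuration, transition
#' matrix and life table) so that [read_params_yaml()] reproduces the
#' parameter set exactly.
#'
#' @param params An [spms_parameters()] object.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_params_yaml <- function(params, path) {
  x <- list(
    cohort = list(
      start_age = params$cohort$start_age,
      male_fraction = params$cohort$male_fraction,
      baseline_dist = as.list(params$cohort$baseline_dist)
    ),
    settings = params$settings,
    edss = as.list(params$edss),
    arms = as.list(params$arms),
    cdp3 = as.list(params$cdp3),
    funnel = as.list(params$funnel),
    national_population = params$national_population,
    bia_costs = list(
      ocrelizumab = params$bia_costs$ocrelizumab,
      ae_cost_annual = as.list(params$bia_costs$ae_cost_annual)
    ),
    synth = unclass(params$synth),
    transition = apply(params$transition, 1, as.list, simplify = FALSE),
    life_table = as.list(params$life_table)
  )
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

# Numbers serialised through text may use the Italian convention
# ("1.720,50"); convert explicitly, never by guessing.
parse_number_locale <- function(x, decimal_mark = ".") {
  if (is.numeric(x)) {
    return(x)
  }
  if (decimal_mark == ",") {
    x <- gsub(".", "", x, fixed = TRUE)
    x <- gsub(",", ".", x, fixed = TRUE)
  } else {
    x <- gsub(",", "", x, fixed = TRUE)
  }
  as.numeric(x)
}

#' Load and validate a parameter set from YAML
#'
#' Reads a file written by [write_params_yaml()] (or hand-edited in the same
#' schema), fills defaults for omitted settings, checks every structural
#' invariant and reports violations with field paths. Monetary values may be
#' given as strings in either plain-dot or Italian decimal convention,
#' selected explicitly by `decimal_mark`.
#'
#' @param path YAML file path.
#' @param decimal_mark `"."` (default) or `","` for Italian-style numbers.
#' @return A validated `spms_params` object.
#' @export
read_params_yaml <- function(path, decimal_mark = ".") {
  if (!file.exists(path)) {
    abort(sprintf("config file not found: %s", path), class = "spmscea_config_error")
  }
  x <- yaml::read_yaml(path)
  need <- function(name) {
    if (is.null(x[[name]])) {
      abort(sprintf("missing required config section [%s]", name),
        class = "spmscea_validation_error"
      )
    }
    x[[name]]
  }
  num <- function(v) parse_number_locale(v, decimal_mark)
  co <- need("cohort")
  for (f in c("start_age", "male_fraction", "baseline_dist")) {
    if (is.null(co[[f]])) {
      abort(sprintf("missing required field [cohort$%s]", f),
        class = "spmscea_validation_error"
      )
    }
  }
  edss <- as_tibble(lapply(need("edss"), num))
  arms_raw <- need("arms")
  arms <- as_tibble(c(arms_raw["arm"], lapply(arms_raw[setdiff(names(arms_raw), "arm")], num)))
  defaults <- list(
    discount_rate = 0.03, wtp = 40000, horizon = 52, stop_edss = 7,
    relapse_cost = 405, half_cycle = FALSE, admin_year1_by = "model_time",
    baseline_discontinuation = 0.10
  )
  settings <- modifyList(defaults, x$settings %||% list())
  synth <- do.call(synth_config, x$synth %||% list())
  tr_list <- x$transition
  transition <- if (is.null(tr_list)) {
    gen_transition_matrix(synth)
  } else {
    m <- do.call(rbind, lapply(tr_list, function(r) num(unlist(r))))
    dimnames(m) <- list(paste0("edss", 0:9), paste0("edss", 0:9))
    m
  }
  life_table <- if (is.null(x$life_table)) {
    gen_life_table(synth)
  } else {
    as_tibble(lapply(x$life_table, num))
  }
  cdp3 <- if (is.null(x$cdp3)) cdp3_inputs() else {
    as_tibble(c(x$cdp3["arm"], lapply(x$cdp3[setdiff(names(x$cdp3), "arm")], num)))
  }
  funnel <- if (is.null(x$funnel)) funnel_inputs() else as_tibble(x$funnel)
  bia <- if (is.null(x$bia_costs)) bia_cost_inputs() else {
    list(
      ocrelizumab = lapply(x$bia_costs$ocrelizumab, num),
      ae_cost_annual = unlist(lapply(x$bia_costs$ae_cost_annual, num))
    )
  }
  p <- structure(
    list(
      cohort = list(
        start_age = num(co$start_age),
        male_fraction = num(co$male_fraction),
        baseline_dist = setNames(
          num(unlist(co$baseline_dist)),
          names(unlist(co$baseline_dist))
        )
      ),
      edss = edss,
      arms = arms,
      cdp3 = cdp3,
      funnel = funnel,
      national_population = num(x$national_population %||% 59641488),
      bia_costs = bia,
      settings = settings,
      synth = synth,
      transition = transition,
      life_table = life_table
    ),
    class = "spms_params"
  )
  validate_params(p)
}

#' Analysis run configuration
#'
#' Bundles what a single command-line run needs: the analysis to perform,
#' the input configuration path (optional; packaged defaults otherwise), the
#' output directory, the seed, the PSA replicate count, and the
#' willingness-to-pay and discount-rate settings.
#'
#' @param analysis One of `"cea"`, `"owsa"`, `"psa"`, `"cdp3"`, `"bia"`.
#' @param config Optional path to a parameters YAML; must exist if given.
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @param psa_replicates PSA replicate count.
#' @param wtp EUR per QALY.
#' @param discount_rate Annual discount rate.
#' @return A list of class `run_config`.
#' @export
run_config <- function(analysis,
                       config = NULL,
                       out_dir = ".",
                       seed = 1,
                       psa_replicates = 5000,
                       wtp = 40000,
                       discount_rate = 0.03) {
  analysis <- match.arg(analysis, c("cea", "owsa", "psa", "cdp3", "bia"))
  if (!is.null(config) && !file.exists(config)) {
    abort(sprintf("config path does not exist: %s", config),
      class = "spmscea_config_error"
    )
  }
  structure(
    list(
      analysis = analysis, config = config, out_dir = out_dir, seed = seed,
      psa_replicates = psa_replicates, wtp = wtp, discount_rate = discount_rate
    ),
    class = "run_config"
  )
}

#' Write analysis results and a reproducibility manifest to disk
#'
#' Writes deterministic CSV layouts for whichever result objects are
#' supplied (CEA summary shaped like the published results table, per-year
#' budget-impact table, tornado, CEAC) plus a JSON manifest carrying the
#' seed, a hash of the parameter set and the package version, from which the
#' run can be reproduced.
#'
#' @param results Named list; recognised names: `cea`, `cdp3`, `bia`,
#'   `owsa`, `ceac`, `psa`.
#' @param out_dir Output directory (created if needed).
#' @param params The `spms_params` used (hashed into the manifest).
#' @param seed The seed used.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(results, out_dir, params = NULL, seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  put <- function(name, writer) {
    if (!is.null(results[[name]])) {
      f <- file.path(out_dir, paste0(name, ".csv"))
      writer(results[[name]], f)
      paths <<- c(paths, f)
    }
  }
  put("cea", write_cea_csv)
  put("cdp3", write_cea_csv)
  put("bia", write_bia_csv)
  put("owsa", function(x, f) readr::write_csv(as_tibble(x), f))
  put("ceac", function(x, f) readr::write_csv(as_tibble(x), f))
  put("psa", function(x, f) readr::write_csv(as_tibble(x), f))
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(
    list(
      seed = seed,
      config_hash = if (!is.null(params)) rlang::hash(params) else NULL,
      package_version = as.character(utils::packageVersion("spmscea")),
      written = basename(paths)
    ),
    mf,
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(c(paths, mf))
}
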