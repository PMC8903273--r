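#' Combined annual death probability at an age, sex mix and EDSS level
#'
#' Background mortality is read from the life table and weighted by the
#' cohort's sex mix; the EDSS-specific excess mortality (rate ratio, 1.00 at
#' EDSS 0) is applied on the rate scale, `q' = 1 - (1 - q)^multiplier`, and
#' the result is capped at 1. Ages beyond the table abort.
#'
#' @param age Age in years (rounded down to the table's integer grid).
#' @param male_fraction Proportion of males in the cohort.
#' @param edss EDSS level(s), 0--9; vectorised.
#' @param life_table Tibble with `age`, `q_female`, `q_male`.
#' @param mort_mult Length-10 vector of rate ratios by EDSS (index 1 = EDSS 0).
#' @return Annual death probability, same length as `edss`.
#' @export
death_probability <- function(age, male_fraction, edss, life_table, mort_mult) {
  if (male_fraction < 0 || male_fraction > 1) {
    abort("male_fraction must be in [0, 1]", class = "spmscea_parameter_error")
  }
  a <- floor(age)
  idx <- match(a, life_table$age)
  if (is.na(idx)) {
    abort(sprintf("age %s outside the life table range [%d, %d]",
      format(age), min(life_table$age), max(life_table$age)
    ), class = "spmscea_range_error")
  }
  q <- male_fraction * life_table$q_male[idx] +
    (1 - male_fraction) * life_table$q_female[idx]
  mult <- mort_mult[edss + 1]
  pmin(1, 1 - (1 - q)^mult)
}
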