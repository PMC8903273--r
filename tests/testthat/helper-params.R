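# Shared fixtures, built in code.

default_params <- function(...) spms_parameters(seed = 2022, ...)

# A 10x10 matrix with a single upward move out of EDSS 0, for closed-form
# checks on the hazard-ratio adjustment.
single_row_matrix <- function(stay = 0.8, up = 0.2) {
  m <- diag(10)
  m[1, 1] <- stay
  m[1, 2] <- up
  dimnames(m) <- list(paste0("edss", 0:9), paste0("edss", 0:9))
  m
}

# A flat life table with constant annual death probability (0 by default),
# for fixed-point and conservation checks.
flat_life_table <- function(q = 0) {
  tibble::tibble(age = 18:200, q_female = q, q_male = q)
}

# Hand-built cohort trace rows for accumulate() unit checks.
blank_trace <- function(n_rows) {
  cols <- c(paste0("on_edss", 0:9), paste0("off_edss", 0:9), "dead")
  tr <- tibble::as_tibble(matrix(0, n_rows, 21, dimnames = list(NULL, cols)))
  dplyr::mutate(tr, cycle = dplyr::row_number() - 1L, age = 48 + cycle, .before = 1)
}
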