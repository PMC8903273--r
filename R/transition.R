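#' Validate an annual EDSS transition matrix
#'
#' A valid matrix is 10x10 (EDSS 0--9), has every entry in \[0, 1\] and every
#' row summing to 1 within 1e-12. Death is handled separately by the cycle
#' operator, so the matrix covers live-state moves only.
#'
#' @param m A numeric matrix.
#' @return `m` invisibly.
#' @export
validate_transition_matrix <- function(m) {
  if (!is.matrix(m) || nrow(m) != 10 || ncol(m) != 10) {
    abort("transition matrix must be 10x10 (EDSS 0-9)", class = "spmscea_matrix_error")
  }
  if (any(m < 0) || any(m > 1)) {
    abort("transition matrix entries must lie in [0, 1]", class = "spmscea_matrix_error")
  }
  if (any(abs(rowSums(m) - 1) > 1e-12)) {
    abort("transition matrix rows must sum to 1 (within 1e-12)",
      class = "spmscea_matrix_error"
    )
  }
  invisible(m)
}

#' Apply a progression hazard ratio to a transition matrix
#'
#' Treatment efficacy enters the model as a hazard ratio on confirmed
#' disability progression. For each row, the aggregate probability `p` of
#' moving to any strictly higher EDSS level is rescaled on the rate scale,
#' `p' = 1 - (1 - p)^hr`, and redistributed over the higher destinations in
#' proportion to their original shares; the change in mass is absorbed by the
#' stay probability. Probabilities of moving to lower levels are untouched,
#' so the result stays row-stochastic. `hr = 1` returns the input unchanged
#' (bitwise).
#'
#' @param matrix A valid 10x10 transition matrix.
#' @param hr Positive hazard ratio versus the matrix's own (placebo) arm.
#' @return The adjusted transition matrix.
#' @export
adjust_progression <- function(matrix, hr) {
  if (!is.numeric(hr) || length(hr) != 1 || is.na(hr) || hr <= 0) {
    abort("hr must be a single positive number", class = "spmscea_parameter_error")
  }
  validate_transition_matrix(matrix)
  if (hr == 1) {
    return(matrix)
  }
  out <- matrix
  n <- nrow(matrix)
  for (i in seq_len(n)) {
    up <- seq_len(n) > i
    p <- sum(matrix[i, up])
    if (p <= 0) next
    p_new <- 1 - (1 - p)^hr
    out[i, up] <- matrix[i, up] * (p_new / p)
    out[i, i] <- matrix[i, i] + (p - p_new)
  }
  out
}

#' Read a transition matrix from CSV
#'
#' Expects a 10x10 layout with a header row of EDSS levels and a first column
#' of row labels (EDSS levels), values being annual probabilities.
#'
#' @param path CSV file path.
#' @return A validated 10x10 matrix.
#' @export
read_transition_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "double"
  validate_transition_matrix(m)
  m
}

#' Write a transition matrix to CSV
#'
#' @param m A 10x10 transition matrix.
#' @param path Destination path.
#' @return `path` invisibly.
#' @export
write_transition_csv <- function(m, path) {
  d <- as_tibble(m, rownames = "edss")
  readr::write_csv(d, path)
  invisible(path)
}
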