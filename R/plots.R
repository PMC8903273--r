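#' Tornado diagram of the one-way sensitivity analysis
#'
#' Horizontal bars spanning the net monetary benefit at each parameter's low
#' and high bound, around the base-case NMB, most influential parameter on
#' top.
#'
#' @param object An `owsa_result`.
#' @param top Show only the `top` widest bars (default all).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.owsa_result <- function(object, top = NULL, ...) {
  d <- as_tibble(object)
  if (!is.null(top)) d <- d[seq_len(min(top, nrow(d))), ]
  d$parameter <- factor(d$parameter, levels = rev(d$parameter))
  ggplot2::ggplot(d) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$nmb_low, xend = .data$nmb_high,
      y = .data$parameter, yend = .data$parameter
    ), linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = attr(object, "nmb_base"), linetype = 2) +
    ggplot2::labs(
      x = sprintf("Net monetary benefit (EUR, WTP %s/QALY)",
        format(attr(object, "wtp"), big.mark = ",")
      ),
      y = NULL, title = "One-way sensitivity analysis"
    ) +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curve plot
#'
#' @param object A `ceac_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ceac_result <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(
    x = .data$wtp, y = .data$probability, colour = .data$arm
  )) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "Willingness to pay (EUR per QALY)",
      y = "Probability cost-effective", colour = NULL,
      title = "Cost-effectiveness acceptability curve"
    ) +
    ggplot2::theme_minimal()
}

#' Cohort trace occupancy plot
#'
#' Stacked state occupancy (on-treatment, off-treatment, dead) over model
#' cycles.
#'
#' @param object A `cohort_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cohort_trace <- function(object, ...) {
  d <- tidy(object) |>
    group_by(.data$cycle, .data$branch) |>
    summarise(occupancy = sum(.data$occupancy), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$cycle, y = .data$occupancy, fill = .data$branch
  )) +
    ggplot2::geom_area() +
    ggplot2::labs(
      x = "Model cycle (years)", y = "Cohort fraction", fill = NULL,
      title = "Cohort occupancy by treatment status"
    ) +
    ggplot2::theme_minimal()
}

#' Annual budget-impact plot
#'
#' @param object A `bia_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bia_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(
    x = factor(.data$year), y = .data$difference / 1e6
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(
      x = "Year", y = "Budget difference (EUR millions)",
      title = "Budget impact of siponimod market entry"
    ) +
    ggplot2::theme_minimal()
}
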