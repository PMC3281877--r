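#' Cost-effectiveness plane scatter of PSA samples
#'
#' @param samples An `fpcea_psa` tibble from [run_psa()].
#' @param perspective `"societal"` or `"moh"`.
#' @return A ggplot object: incremental DALE (x) vs incremental cost (y),
#'   one point per Monte-Carlo iteration, axes through the origin.
#' @export
plot_ce_plane <- function(samples, perspective = c("societal", "moh")) {
  perspective <- match.arg(perspective)
  y <- paste0("delta_cost_", perspective)
  ggplot2::ggplot(samples, ggplot2::aes(x = .data$delta_dale, y = .data[[y]])) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::labs(
      x = "Incremental DALE (years per woman)",
      y = sprintf("Incremental cost (US$ per woman, %s)", perspective),
      title = "Cost-effectiveness plane"
    ) +
    ggplot2::theme_minimal()
}

#' Tornado diagram of one-way sensitivity results
#'
#' @param torn An `fpcea_tornado` tibble from [tornado()].
#' @param n_top Number of most influential parameters to display.
#' @return A ggplot object: horizontal bars from the low-bound output to the
#'   high-bound output, widest on top, with the base-case value marked.
#' @export
plot_tornado <- function(torn, n_top = 12) {
  d <- utils::head(torn, n_top)
  d$id <- factor(d$id, levels = rev(d$id))
  ggplot2::ggplot(d) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$low_output, xend = .data$high_output,
                   y = .data$id, yend = .data$id),
      linewidth = 4, colour = "steelblue"
    ) +
    ggplot2::geom_vline(xintercept = d$base_output[1], linetype = 2) +
    ggplot2::labs(x = attr(torn, "output") %||% "output", y = NULL,
                  title = "One-way sensitivity (tornado)") +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curve plot
#'
#' @param curve A tibble from [ceac()] (columns `threshold`, `probability`).
#' @return A ggplot object of acceptability probability against the
#'   willingness-to-pay threshold.
#' @export
plot_ceac <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$threshold, y = .data$probability)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (US$ per DALY averted)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}

#' State-occupancy ribbon plot of a cohort trace
#'
#' @param object An `fpcea_trace` from [run_cohort()].
#' @param ... Unused.
#' @return A ggplot object: state-occupancy fractions by age.
#' @method autoplot fpcea_trace
#' @export
autoplot.fpcea_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[c("age", tolower(STATES))],
    -"age", names_to = "state", values_to = "occupancy"
  )
  long$state <- factor(toupper(long$state), levels = STATES)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$age, y = .data$occupancy,
                                     fill = .data$state)) +
    ggplot2::geom_area() +
    ggplot2::labs(x = "Age (years)", y = "Cohort fraction",
                  fill = "State",
                  title = sprintf("Cohort trace (%s)", attr(object, "scenario"))) +
    ggplot2::theme_minimal()
}
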