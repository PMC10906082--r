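# ggplot2 presentations of the analysis result types. These return plain
# ggplot objects built from the plot-ready tables; styling is left to the
# caller.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tornado diagram of a one-way sensitivity analysis
#'
#' @param object A `cea_dsa` from [one_way_dsa()].
#' @param ... Unused.
#' @return A ggplot object: horizontal bars from the low-bound to the
#'   high-bound ICER per parameter, widest spread on top, with the base-case
#'   ICER as a reference line.
#' @method autoplot cea_dsa
#' @export
autoplot.cea_dsa <- function(object, ...) {
  df <- dplyr::mutate(
    tibble::as_tibble(object),
    parameter = stats::reorder(.data$parameter, .data$spread)
  )
  ggplot2::ggplot(df, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$icer_low,
                                       xend = .data$icer_high,
                                       yend = .data$parameter),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = attr(object, "icer_base"),
                        linetype = "dashed") +
    ggplot2::labs(x = "ICER ($/QALY)", y = NULL,
                  title = "One-way sensitivity analysis")
}

#' Cost-effectiveness acceptability curves
#'
#' @param object A `cea_ceac` from [ceac()].
#' @param ... Unused.
#' @return A ggplot object: probability cost-effective versus
#'   willingness-to-pay, one curve per strategy.
#' @method autoplot cea_ceac
#' @export
autoplot.cea_ceac <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$wtp, y = .data$probability,
                                       colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay ($/QALY)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curves")
}

#' Incremental cost-effectiveness scatter
#'
#' @param object A `cea_scatter` from [ce_scatter()].
#' @param wtp Optional willingness-to-pay threshold drawn as a line through
#'   the origin.
#' @param ... Unused.
#' @return A ggplot object of the per-iteration incremental pairs on the
#'   cost-effectiveness plane.
#' @method autoplot cea_scatter
#' @export
autoplot.cea_scatter <- function(object, wtp = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$delta_qalys,
                                            y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.4, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::geom_vline(xintercept = 0) +
    ggplot2::labs(x = expression(Delta ~ "QALYs"),
                  y = expression(Delta ~ "cost ($)"),
                  title = "Probabilistic sensitivity analysis")
  if (!is.null(wtp)) {
    p <- p + ggplot2::geom_abline(slope = wtp, intercept = 0,
                                  linetype = "dashed")
  }
  p
}

#' Cohort trace occupancy over time
#'
#' @param object A `cea_trace` from [run_cohort()].
#' @param ... Unused.
#' @return A stacked-area ggplot of state occupancy by cycle.
#' @method autoplot cea_trace
#' @export
autoplot.cea_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$cycle, y = .data$occupancy,
                                       fill = .data$state)) +
    ggplot2::geom_area() +
    ggplot2::labs(x = "Cycle (months)", y = "Occupancy",
                  title = attr(object, "strategy_label"))
}

#' @rdname autoplot.cea_dsa
#' @param dsa A `cea_dsa`.
#' @export
plot_tornado <- function(dsa, ...) autoplot(dsa, ...)

#' @rdname autoplot.cea_ceac
#' @param curves A `cea_ceac`.
#' @export
plot_ceac <- function(curves, ...) autoplot(curves, ...)

#' @rdname autoplot.cea_scatter
#' @param scatter A `cea_scatter`.
#' @export
plot_ce_scatter <- function(scatter, wtp = NULL, ...) autoplot(scatter, wtp = wtp, ...)
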