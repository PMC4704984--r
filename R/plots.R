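#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Cost-effectiveness plane
#'
#' Scatter of per-iteration incremental effect (x) versus incremental cost
#' (y) of each comparator against the reference strategy, with the
#' willingness-to-pay threshold drawn through the origin.
#'
#' @param object a `cea_psa`.
#' @param reference reference strategy (default `"myCompass"`).
#' @param wtp willingness-to-pay line to draw (AUD/QALY).
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.cea_psa <- function(object, reference = "myCompass",
                             wtp = object$config$wtp_default, ...) {
  d <- export_ce_plane(object, reference = reference, path = NULL)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$delta_qaly,
                                  y = .data$delta_cost_aud,
                                  colour = .data$comparator)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::geom_abline(slope = wtp, intercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = sprintf("Incremental QALYs (vs %s)", reference),
      y = sprintf("Incremental cost, AUD (vs %s)", reference),
      colour = "Comparator",
      title = "Cost-effectiveness plane",
      subtitle = sprintf("dashed line: WTP = AUD %s/QALY",
                         format(wtp, big.mark = ","))
    ) +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curves
#'
#' @param object a `cea_ceac` from [ceac()].
#' @param ... unused.
#' @return A ggplot of the probability each strategy has the highest net
#'   monetary benefit, as a function of willingness-to-pay.
#' @export
autoplot.cea_ceac <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$wtp, y = .data$probability,
                                       colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay, AUD/QALY",
                  y = "Probability of highest NMB",
                  colour = "Strategy",
                  title = "Cost-effectiveness acceptability curves") +
    ggplot2::theme_minimal()
}

#' One-way sensitivity sweep
#'
#' @param object a `cea_oneway` from [one_way()].
#' @param ... unused.
#' @return A ggplot of the optimal strategy's expected NMB across the sweep,
#'   coloured by which strategy is optimal.
#' @export
autoplot.cea_oneway <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$value,
                                       y = .data$expected_nmb)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$optimal_strategy),
                        size = 0.9) +
    ggplot2::labs(x = object$parameter[1], y = "Expected NMB, AUD",
                  colour = "Optimal strategy",
                  title = "One-way sensitivity analysis") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.cea_psa
#' @param psa a `cea_psa`.
#' @export
plot_ce_plane <- function(psa, reference = "myCompass",
                          wtp = psa$config$wtp_default) {
  autoplot.cea_psa(psa, reference = reference, wtp = wtp)
}

#' @rdname autoplot.cea_ceac
#' @param x a `cea_ceac`.
#' @export
plot_ceac <- function(x) autoplot.cea_ceac(x)
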