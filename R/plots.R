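#' Plot conditional bias by true ability level
#'
#' Line plot of conditional bias against the true ability level, one colour
#' per approach, with a +/- 2 Monte Carlo SE ribbon.
#'
#' @param summary_tbl A [condition_summary()] tibble.
#' @return A ggplot object.
#' @export
plot_conditional_bias <- function(summary_tbl) {
  ggplot2::ggplot(summary_tbl,
                  ggplot2::aes(x = .data$true_theta, y = .data$bias,
                               colour = .data$approach,
                               fill = .data$approach)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$bias - 2 * .data$se_bias,
                                      ymax = .data$bias + 2 * .data$se_bias),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = expression(theta), y = "Conditional bias",
                  colour = "Approach", fill = "Approach") +
    ggplot2::theme_minimal()
}

#' Plot conditional MSE by true ability level
#'
#' @inheritParams plot_conditional_bias
#' @return A ggplot object.
#' @export
plot_conditional_mse <- function(summary_tbl) {
  ggplot2::ggplot(summary_tbl,
                  ggplot2::aes(x = .data$true_theta, y = .data$mse,
                               colour = .data$approach,
                               fill = .data$approach)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mse - 2 * .data$se_mse,
                                      ymax = .data$mse + 2 * .data$se_mse),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = expression(theta), y = "Conditional MSE",
                  colour = "Approach", fill = "Approach") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Trajectory plot of one CAT session
#'
#' Provisional ability estimate after each administered item, with a
#' +/- 2 SE band and the true ability as a reference line.
#'
#' @param object A [administer_cat()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cat_result <- function(object, ...) {
  tr <- object$trace
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$t, y = .data$est)) +
    ggplot2::geom_hline(yintercept = object$true_theta, linetype = 2,
                        colour = "grey40") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$est - 2 * .data$se,
                                      ymax = .data$est + 2 * .data$se),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = factor(.data$u))) +
    ggplot2::scale_shape_manual(values = c(`0` = 1, `1` = 16),
                                name = "Response") +
    ggplot2::labs(x = "Item position", y = "Provisional estimate") +
    ggplot2::theme_minimal()
}
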