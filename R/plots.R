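#' Plot helpers for the standard sweeps
#'
#' Thin ggplot2 wrappers over the tidy tables produced by the experiment
#' runner; used by the command-line tool to render each sweep.
#'
#' @param df A result data frame from [run_experiment()].
#' @return A ggplot object.
#' @name delayq_plots
NULL

#' @rdname delayq_plots
#' @export
plot_queue_sweep <- function(df) {
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cv, y = .data$mean_T,
                                   colour = factor(.data$K),
                                   linetype = .data$method)) +
    ggplot2::geom_line(data = df[df$method != "monte_carlo", ]) +
    ggplot2::geom_point(data = df[df$method == "monte_carlo", ]) +
    ggplot2::labs(x = "delay CV", y = "mean signaling time",
                  colour = "K", linetype = "method")
}

#' @rdname delayq_plots
#' @export
plot_pdf_compare <- function(df) {
  ggplot2::ggplot(df) +
    ggplot2::geom_col(ggplot2::aes(x = (.data$lower + .data$upper) / 2,
                                   y = .data$observed / (.data$upper - .data$lower)),
                      width = df$upper - df$lower, fill = "grey80") +
    ggplot2::geom_step(ggplot2::aes(x = .data$lower,
                                    y = .data$expected / (.data$upper - .data$lower)),
                       colour = "firebrick") +
    ggplot2::labs(x = "signaling time", y = "density")
}

#' @rdname delayq_plots
#' @export
plot_ffl_pulse <- function(df) {
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sigma, y = .data$pulse,
                                   colour = .data$mode)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$pulse - 2 * .data$se,
                                          ymax = .data$pulse + 2 * .data$se)) +
    ggplot2::labs(x = "delay sd", y = "expected pulse duration")
}

#' @rdname delayq_plots
#' @export
plot_oscillator_sweep <- function(df) {
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cv)) +
    ggplot2::geom_pointrange(ggplot2::aes(y = .data$mean_height_sim,
                                          ymin = .data$mean_height_sim - .data$sd_height_sim,
                                          ymax = .data$mean_height_sim + .data$sd_height_sim)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$pred_first), linetype = 2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$pred_refined), linetype = 1) +
    ggplot2::labs(x = "delay CV", y = "mean peak height",
                  caption = "dashed: first-order prediction; solid: refined")
}

#' @importFrom ggplot2 .data
NULL
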