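#' Plot acceleration curves
#'
#' Acceleration factor versus workload, with (dashed) and without (solid)
#' inter-node communication.
#'
#' @param object an `accel_curve` from [accel_curve()].
#' @param log_y log-scale the acceleration axis.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.accel_curve <- function(object, log_y = TRUE, ...) {
  long <- tidyr::pivot_longer(object, c("F_S", "F_C"),
                              names_to = "model", values_to = "accel")
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$nu_bar_k, .data$accel,
                                          linetype = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::scale_linetype_manual(
      values = c(F_S = "solid", F_C = "dashed"),
      labels = c(F_S = "without communication", F_C = "with communication")) +
    ggplot2::labs(x = "spike events per step",
                  y = "acceleration factor (x real time)",
                  linetype = NULL)
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot the performance-loss decomposition
#'
#' Stacked contributions of node-local presynaptic data processing (`P_S`)
#' and inter-node communication (`P_C`) to the total loss relative to the
#' maximum single-node acceleration.
#'
#' @param cfg a [latency_config()].
#' @param nu_max,step workload grid.
#' @return a ggplot.
#' @export
plot_perf_loss <- function(cfg = latency_config(), nu_max = 30, step = 0.1) {
  loss <- perf_loss(cfg, seq(0, nu_max, by = step))
  long <- tidyr::pivot_longer(loss[, c("nu_bar_k", "P_S", "P_C")],
                              c("P_S", "P_C"),
                              names_to = "component", values_to = "loss")
  ggplot2::ggplot(long, ggplot2::aes(.data$nu_bar_k, .data$loss,
                                     fill = .data$component)) +
    ggplot2::geom_area() +
    ggplot2::labs(x = "spike events per step", y = "performance loss (%)",
                  fill = NULL)
}

#' Spike raster of a simulation
#'
#' @param object an `izh_sim`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.izh_sim <- function(object, ...) {
  ggplot2::ggplot(object$spikes,
                  ggplot2::aes(.data$t_ms, .data$neuron)) +
    ggplot2::geom_point(size = 0.2) +
    ggplot2::labs(x = "time (ms)", y = "neuron id")
}

#' Plot a measure distribution
#'
#' Freedman-Diaconis histogram with the Gaussian-kernel density overlaid.
#'
#' @param object a `measure_distribution`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.measure_distribution <- function(object, ...) {
  if (object$type == "point_mass") {
    return(ggplot2::ggplot() +
             ggplot2::geom_vline(xintercept = object$value) +
             ggplot2::labs(x = "value", y = "probability density"))
  }
  ggplot2::ggplot(object$histogram) +
    ggplot2::geom_col(ggplot2::aes(.data$mid, .data$density),
                      width = object$bin_width, alpha = 0.5) +
    ggplot2::geom_line(data = object$density,
                       ggplot2::aes(.data$x, .data$y)) +
    ggplot2::labs(x = "value", y = "probability density")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
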