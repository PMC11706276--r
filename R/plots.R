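#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point labs
#'   facet_wrap theme_minimal stat_function
NULL

#' @export
ggplot2::autoplot

#' Plot simulated current sweeps
#'
#' @param object A `nav_traces` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.nav_traces <- function(object, ...) {
  proto <- attr(object, "protocol")
  ggplot(object, aes(x = .data$time_ms, y = .data$i_pA,
                     group = .data$sweep, colour = .data$sweep)) +
    geom_line(linewidth = 0.3) +
    labs(x = "time (ms)", y = "current (pA)", colour = "sweep",
         title = if (is.null(proto)) NULL else paste0(proto$name, " protocol")) +
    theme_minimal()
}

#' Plot a peak current-density/voltage relationship
#'
#' @param iv Tibble from [peak_iv()].
#' @return A ggplot.
#' @export
plot_iv <- function(iv) {
  ggplot(iv, aes(x = .data$v_mV, y = .data$density_pA_per_pF)) +
    geom_line() + geom_point() +
    labs(x = "membrane potential (mV)", y = "current density (pA/pF)") +
    theme_minimal()
}

#' Plot a Boltzmann fit over its points
#'
#' @param object A `boltzmann_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.boltzmann_fit <- function(object, ...) {
  s <- if (object$direction == "rising") 1 else -1
  vh <- object$v_half; k <- object$k
  ggplot(object$data, aes(x = .data$v, y = .data$y)) +
    geom_point() +
    stat_function(fun = function(v) 1 / (1 + exp(-s * (v - vh) / k))) +
    labs(x = "membrane potential (mV)", y = "normalized G or availability") +
    theme_minimal()
}

#' Plot a recovery fit over its points
#'
#' @param object A `recovery_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.recovery_fit <- function(object, ...) {
  tau <- object$tau; A <- object$amplitude
  ggplot(object$data, aes(x = .data$t, y = .data$y)) +
    geom_point() +
    stat_function(fun = function(t) 1 - A * exp(-t / tau)) +
    labs(x = "interpulse interval (ms)", y = "recovered fraction") +
    theme_minimal()
}

#' Plot a hybrid-neuron sweep (membrane potential and currents)
#'
#' @param object A `dapc_sim` tibble.
#' @param components Include the membrane current components?
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.dapc_sim <- function(object, components = TRUE, ...) {
  long <- object |>
    tidyr::pivot_longer(-"time_ms", names_to = "channel", values_to = "value")
  if (!components) long <- long[long$channel == "vm_mV", ]
  ggplot(long, aes(x = .data$time_ms, y = .data$value)) +
    geom_line(linewidth = 0.3) +
    facet_wrap(~channel, ncol = 1, scales = "free_y") +
    labs(x = "time (ms)", y = NULL) +
    theme_minimal()
}

#' Plot an input-output relationship
#'
#' @param object A `firing_summary` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.firing_summary <- function(object, ...) {
  ggplot(object, aes(x = .data$stim_pA, y = .data$mean_freq_hz)) +
    geom_line() + geom_point(aes(shape = .data$sustained)) +
    labs(x = "stimulus current (pA)", y = "mean firing frequency (Hz)") +
    theme_minimal()
}
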