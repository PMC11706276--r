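#' Construct an episodic voltage-clamp protocol
#'
#' A protocol is a holding potential plus an ordered list of per-sweep
#' segments. One segment may be swept: either its command level
#' (`role = "swept_level"`, used by IV and availability protocols) or its
#' duration (`role = "swept_duration"`, used by the paired-pulse recovery
#' protocol). `sweep_values` supplies the per-sweep value of that segment.
#'
#' @param name Protocol label.
#' @param holding_mV Holding potential between sweeps, mV.
#' @param segments A data frame with columns `segment` (label),
#'   `level_mV` (command level; `NA` for the swept-level segment),
#'   `duration_ms` (`NA` for the swept-duration segment), and
#'   `role` (`"fixed"`, `"swept_level"` or `"swept_duration"`).
#' @param sweep_values Numeric vector, strictly monotone, one per sweep.
#' @param sample_rate_hz Sampling rate, Hz.
#' @return An object of class `voltage_protocol`.
#' @export
voltage_protocol <- function(name, holding_mV, segments, sweep_values,
                             sample_rate_hz = 50000) {
  segments <- as_tibble(segments)
  stopifnot(all(c("segment", "level_mV", "duration_ms", "role") %in% names(segments)))
  if (length(sweep_values) == 0L) stop("sweep_values must be non-empty", call. = FALSE)
  d <- diff(sweep_values)
  if (length(d) && !(all(d > 0) || all(d < 0))) {
    stop("sweep_values must be strictly monotone", call. = FALSE)
  }
  fixed_dur <- segments$duration_ms[segments$role != "swept_duration"]
  if (any(!is.finite(fixed_dur)) || any(fixed_dur <= 0)) {
    stop("segment durations must be positive", call. = FALSE)
  }
  n_swept <- sum(segments$role != "fixed")
  if (n_swept > 1L) stop("at most one segment may be swept", call. = FALSE)
  if (any(segments$role == "swept_duration") && any(sweep_values <= 0)) {
    stop("swept durations must be positive", call. = FALSE)
  }
  structure(
    list(name = name, holding_mV = holding_mV, segments = segments,
         sweep_values = as.numeric(sweep_values), sample_rate_hz = sample_rate_hz),
    class = "voltage_protocol"
  )
}

#' @export
print.voltage_protocol <- function(x, ...) {
  cat(sprintf("<voltage_protocol> %s: HP %g mV, %d segments, %d sweeps @ %g kHz\n",
              x$name, x$holding_mV, nrow(x$segments), length(x$sweep_values),
              x$sample_rate_hz / 1000))
  invisible(x)
}

#' Activation (peak IV) protocol
#'
#' From a holding potential of -120 mV, depolarizing steps of 40 ms duration
#' in 5 mV increments between -80 and +55 mV (28 sweeps), with short
#' baseline and tail segments at the holding potential.
#'
#' @param holding_mV Holding potential, mV.
#' @return A `voltage_protocol`.
#' @export
protocol_activation <- function(holding_mV = -120) {
  voltage_protocol(
    name = "activation",
    holding_mV = holding_mV,
    segments = tibble(
      segment = c("baseline", "step", "tail"),
      level_mV = c(holding_mV, NA, holding_mV),
      duration_ms = c(2, 40, 2),
      role = c("fixed", "swept_level", "fixed")
    ),
    sweep_values = seq(-80, 55, by = 5)
  )
}

#' Steady-state inactivation (availability) protocol
#'
#' Preconditioning steps of 100 ms duration in 5 mV increments between -80
#' and +20 mV (21 sweeps), each followed by a 20 ms test pulse to -10 mV that
#' probes the remaining sodium-current availability.
#'
#' @inheritParams protocol_activation
#' @return A `voltage_protocol`.
#' @export
protocol_inactivation <- function(holding_mV = -120) {
  voltage_protocol(
    name = "inactivation",
    holding_mV = holding_mV,
    segments = tibble(
      segment = c("baseline", "prepulse", "test", "tail"),
      level_mV = c(holding_mV, NA, -10, holding_mV),
      duration_ms = c(2, 100, 20, 2),
      role = c("fixed", "swept_level", "fixed", "fixed")
    ),
    sweep_values = seq(-80, 20, by = 5)
  )
}

#' Paired-pulse recovery protocol
#'
#' P1 (20 ms at -10 mV) develops inactivation; the channel then recovers at
#' the -120 mV holding potential for a swept interval t before P2 (20 ms at
#' -10 mV) probes how much availability has returned. Intervals are
#' log-spaced from 0.1 to 30 ms; t = 0.1 ms is always included because the
#' inactivated-fraction analysis mode normalizes to it.
#'
#' @inheritParams protocol_activation
#' @param intervals_ms Interpulse intervals, ms.
#' @return A `voltage_protocol`.
#' @export
protocol_recovery <- function(holding_mV = -120,
                              intervals_ms = c(0.1, 0.2, 0.5, 1, 2, 3, 5, 8, 12, 20, 30)) {
  voltage_protocol(
    name = "recovery",
    holding_mV = holding_mV,
    segments = tibble(
      segment = c("baseline", "p1", "interpulse", "p2", "tail"),
      level_mV = c(holding_mV, -10, holding_mV, -10, holding_mV),
      duration_ms = c(2, 20, NA, 20, 2),
      role = c("fixed", "fixed", "swept_duration", "fixed", "fixed")
    ),
    sweep_values = intervals_ms
  )
}

#' The standard protocol set
#'
#' @return Named list with elements `activation`, `inactivation`, `recovery`.
#' @export
standard_protocols <- function() {
  list(
    activation = protocol_activation(),
    inactivation = protocol_inactivation(),
    recovery = protocol_recovery()
  )
}
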