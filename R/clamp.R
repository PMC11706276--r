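#' Whole-cell recording conditions
#'
#' @param c_m_pF Cell capacitance, pF (> 0). Used to convert peak currents to
#'   densities.
#' @param v_rev_mV Reversal potential used by the conductance transform
#'   `G = I / (V - V_rev)`; `NULL` uses the variant's `e_na_mV`.
#' @param g_max_nS Total maximal conductance of the expressed channels;
#'   `NULL` calibrates it so the simulated inward peak density at -10 mV
#'   equals the variant's `peak_density_pA_per_pF`.
#' @return An object of class `recording_conditions`.
#' @export
recording_conditions <- function(c_m_pF = 10, v_rev_mV = NULL, g_max_nS = NULL) {
  if (!is.numeric(c_m_pF) || c_m_pF <= 0) stop("c_m_pF must be > 0", call. = FALSE)
  structure(list(c_m_pF = c_m_pF, v_rev_mV = v_rev_mV, g_max_nS = g_max_nS),
            class = "recording_conditions")
}

resolve_sweep_segments <- function(protocol, value) {
  seg <- protocol$segments
  lev <- seg$level_mV
  dur <- seg$duration_ms
  lev[seg$role == "swept_level"] <- value
  dur[seg$role == "swept_duration"] <- value
  tibble(segment = seg$segment, level_mV = lev, duration_ms = dur)
}

#' Simulate a voltage-clamp protocol on a variant channel
#'
#' The command voltage is imposed exactly (ideal clamp, leak-free); within
#' each constant-voltage segment the gates follow their closed-form
#' exponential relaxation, which is the exponential-Euler update composed
#' over the whole segment. Gates start at steady state for the holding
#' potential. Sampling is uniform at `dt`; all segment durations must be
#' (near) multiples of `dt`.
#'
#' @param params A [variant_params()] object (or coercible).
#' @param protocol A [voltage_protocol()].
#' @param cond [recording_conditions()]; `g_max_nS = NULL` triggers density
#'   calibration.
#' @param dt Sample interval, ms (<= 0.02, i.e. >= 50 kHz).
#' @return A tibble of class `nav_traces` with columns `sweep` (the swept
#'   value), `segment`, `time_ms`, `v_mV`, `i_pA`, and attributes `protocol`,
#'   `conditions`, `params`, `dt`.
#' @export
run_voltage_clamp <- function(params, protocol, cond = recording_conditions(),
                              dt = 0.02) {
  params <- as_variant_params(params)
  stopifnot(inherits(protocol, "voltage_protocol"))
  if (!is.numeric(dt) || dt <= 0 || dt > 0.02 + 1e-12) {
    stop("`dt` must be positive and at most 0.02 ms (>= 50 kHz)", call. = FALSE)
  }
  if (is.null(cond$g_max_nS)) {
    cond$g_max_nS <- calibrate_gmax(params, cond, dt = dt)
  }
  v_rev <- if (is.null(cond$v_rev_mV)) params$e_na_mV else cond$v_rev_mV
  g <- cond$g_max_nS

  sweeps <- purrr::map(protocol$sweep_values, function(val) {
    segs <- resolve_sweep_segments(protocol, val)
    state <- gating_steady_state(params, protocol$holding_mV)
    t0 <- 0
    out <- vector("list", nrow(segs))
    for (j in seq_len(nrow(segs))) {
      v <- segs$level_mV[j]
      n <- max(1L, as.integer(round(segs$duration_ms[j] / dt)))
      tt <- seq_len(n) * dt
      m_inf <- steady_state_activation(params, v)
      h_inf <- steady_state_inactivation(params, v)
      em <- exp(-tt / gate_tau(params, "m", v)[1])
      eh <- exp(-tt / gate_tau(params, "h", v)[1])
      m <- m_inf + (state$m - m_inf) * em
      h <- h_inf + (state$h - h_inf) * eh
      i_pA <- g * m * h * (v - params$e_na_mV)
      if (any(!is.finite(i_pA))) stop("non-finite current during integration", call. = FALSE)
      out[[j]] <- tibble(
        sweep = val, segment = segs$segment[j], time_ms = t0 + tt,
        v_mV = v, i_pA = i_pA
      )
      state <- list(m = m[n], h = h[n])
      t0 <- t0 + n * dt
    }
    dplyr::bind_rows(out)
  })
  traces <- dplyr::bind_rows(sweeps)
  cond$v_rev_mV <- v_rev
  structure(traces,
            class = c("nav_traces", class(traces)),
            protocol = protocol, conditions = cond, params = params, dt = dt)
}

#' Calibrate the maximal conductance to the measured peak density
#'
#' Runs a single 40 ms step to -10 mV with unit conductance and scales so the
#' simulated inward peak current density matches the variant's
#' `peak_density_pA_per_pF` (current scales linearly with conductance).
#'
#' @inheritParams run_voltage_clamp
#' @return Maximal conductance in nS.
#' @export
calibrate_gmax <- function(params, cond = recording_conditions(), dt = 0.02) {
  params <- as_variant_params(params)
  proto <- voltage_protocol(
    name = "gmax-calibration", holding_mV = -120,
    segments = tibble(
      segment = c("baseline", "step"),
      level_mV = c(-120, NA),
      duration_ms = c(2, 40),
      role = c("fixed", "swept_level")
    ),
    sweep_values = -10
  )
  cond$g_max_nS <- 1
  tr <- run_voltage_clamp(params, proto, cond, dt = dt)
  pk <- step_peak(tr$time_ms[tr$segment == "step"], tr$i_pA[tr$segment == "step"])
  if (pk >= 0) stop("calibration step produced no inward current", call. = FALSE)
  params$peak_density_pA_per_pF * cond$c_m_pF / abs(pk)
}

#' Export traces as CSV plus a YAML sidecar
#'
#' Writes a wide CSV (`time_ms`, one `sweep_<value>` column per sweep; sweeps
#' shorter than the longest are NA-padded) and a YAML metadata file holding
#' the protocol name, holding potential, sample rate, variant and seed.
#'
#' @param traces A `nav_traces` tibble.
#' @param path Output CSV path; the sidecar is `<path>.yaml`.
#' @param seed Optional seed recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
export_traces <- function(traces, path, seed = NULL) {
  stopifnot(inherits(traces, "nav_traces"))
  proto <- attr(traces, "protocol")
  params <- attr(traces, "params")
  dt <- attr(traces, "dt")
  by_sweep <- split(traces$i_pA, traces$sweep)
  n_max <- max(lengths(by_sweep))
  wide <- tibble(time_ms = seq_len(n_max) * dt)
  # preserve protocol sweep order, not split()'s alphanumeric order
  for (val in proto$sweep_values) {
    v <- by_sweep[[as.character(val)]]
    wide[[paste0("sweep_", val)]] <- c(v, rep(NA_real_, n_max - length(v)))
  }
  utils::write.csv(wide, path, row.names = FALSE)
  yaml::write_yaml(
    list(protocol = proto$name, holding_mV = proto$holding_mV,
         sample_rate_hz = proto$sample_rate_hz, variant = params$name,
         dt_ms = dt, seed = seed),
    paste0(path, ".yaml")
  )
  invisible(path)
}
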