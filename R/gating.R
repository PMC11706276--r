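#' Boltzmann sigmoid
#'
#' Fractional occupancy of a two-state voltage sensor. The `rising` form,
#' `1 / (1 + exp(-(V - v_half)/k))`, describes activation (increases with
#' depolarization); the `falling` form, `1 / (1 + exp((V - v_half)/k))`,
#' describes availability (decreases with depolarization). `k` is the slope
#' factor in mV and must be positive in either direction.
#'
#' @param v Membrane potential, mV. Vectorized.
#' @param v_half Half-maximal voltage, mV.
#' @param k Slope factor, mV (> 0).
#' @param direction `"rising"` or `"falling"`.
#' @return Fraction strictly in (0, 1), same length as `v`.
#' @export
#' @examples
#' boltzmann_fraction(-17.56, -17.56, 6, "rising") # 0.5 at the midpoint
boltzmann_fraction <- function(v, v_half, k, direction = c("rising", "falling")) {
  direction <- match.arg(direction)
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0) {
    stop("`k` must be a single positive slope factor (mV)", call. = FALSE)
  }
  x <- (v - v_half) / k
  if (direction == "rising") 1 / (1 + exp(-x)) else 1 / (1 + exp(x))
}

#' Steady-state activation of a variant channel
#'
#' Rising Boltzmann with the variant's activation midpoint and slope.
#'
#' @param params A [variant_params()] object.
#' @param v Membrane potential, mV.
#' @return m_inf in (0, 1).
#' @export
steady_state_activation <- function(params, v) {
  params <- as_variant_params(params)
  boltzmann_fraction(v, params$v_half_act_mV, params$k_act_mV, "rising")
}

#' Steady-state inactivation (availability) of a variant channel
#'
#' Falling Boltzmann with the variant's inactivation midpoint and slope,
#' lifted onto the non-inactivating floor `persistent_frac`:
#' `h_inf(V) = pf + (1 - pf) * falling(V, v_half_inact, k_inact)`.
#' The floor is what remains conducting at strongly depolarized potentials
#' and is the model's persistent-current mechanism.
#'
#' @inheritParams steady_state_activation
#' @return h_inf in \[persistent_frac, 1\].
#' @export
steady_state_inactivation <- function(params, v) {
  params <- as_variant_params(params)
  pf <- params$persistent_frac
  pf + (1 - pf) *
    boltzmann_fraction(v, params$v_half_inact_mV, params$k_inact_mV, "falling")
}

# tau_h(V) = A + B * falling(V, -65, 10) + C * bell(V), with the bell a
# product of rising/falling sigmoids peaking near -65 mV. A and B are solved
# per variant so that tau_h(-120) = tau_rec_ms exactly (the paired-pulse
# recovery anchor) and tau_h(-10) = tau_inact_ms (decay during a test step).
TAU_H_BELL_AMP <- 5

tau_h_bell <- function(v) {
  boltzmann_fraction(v, -90, 8, "rising") * boltzmann_fraction(v, -50, 6, "falling")
}

tau_h_ramp <- function(v) boltzmann_fraction(v, -65, 10, "falling")

tau_h_coefs <- function(params) {
  f1 <- tau_h_ramp(-120); b1 <- tau_h_bell(-120)
  f2 <- tau_h_ramp(-10);  b2 <- tau_h_bell(-10)
  rhs1 <- params$tau_rec_ms - TAU_H_BELL_AMP * b1
  rhs2 <- params$tau_inact_ms - TAU_H_BELL_AMP * b2
  B <- (rhs1 - rhs2) / (f1 - f2)
  A <- rhs1 - B * f1
  c(A = A, B = B)
}

#' Voltage-dependent gate time constants
#'
#' Activation (`m`) kinetics are fast and voltage-independent (0.1 ms) so the
#' peak-conductance analysis is unbiased across the fitted voltage range.
#' Inactivation (`h`) kinetics are bell-shaped: slow around -65 mV, anchored
#' exactly to `tau_rec_ms` at the -120 mV recovery potential and to
#' `tau_inact_ms` at the -10 mV test potential.
#'
#' @inheritParams steady_state_activation
#' @param gate `"m"` or `"h"`.
#' @return Time constant in ms, strictly positive, same length as `v`.
#' @export
#' @examples
#' wt <- nav_variant("WT")
#' gate_tau(wt, "h", -120) # equals the recovery time constant, 1.19 ms
gate_tau <- function(params, gate = c("m", "h"), v) {
  gate <- match.arg(gate)
  params <- as_variant_params(params)
  if (gate == "m") {
    return(rep_len(0.1, length(v)))
  }
  co <- tau_h_coefs(params)
  tau <- co[["A"]] + co[["B"]] * tau_h_ramp(v) + TAU_H_BELL_AMP * tau_h_bell(v)
  if (any(tau <= 0)) {
    stop("tau_h(V) is not positive for this parameter set; check tau_rec_ms/tau_inact_ms",
         call. = FALSE)
  }
  tau
}

#' Instantaneous channel current
#'
#' Ohmic driving-force model `I = g_max * m * h * (V - E_Na)`; inward current
#' is negative.
#'
#' @inheritParams steady_state_activation
#' @param m,h Gate values in \[0, 1\].
#' @param g_max Maximal conductance, nS.
#' @return Current in pA.
#' @export
channel_current <- function(params, m, h, v, g_max) {
  params <- as_variant_params(params)
  stopifnot(all(m >= 0 & m <= 1), all(h >= 0 & h <= 1))
  g_max * m * h * (v - params$e_na_mV)
}

#' Advance the gating state at fixed voltage
#'
#' Exponential-Euler update: each gate relaxes exponentially toward its
#' steady state, `x <- x_inf + (x - x_inf) * exp(-dt / tau_x)`. The update is
#' exact for constant voltage, so composing n steps of `dt` equals one step
#' of `n * dt`, and gates can never leave \[0, 1\].
#'
#' @inheritParams steady_state_activation
#' @param state List with elements `m` and `h` in \[0, 1\].
#' @param dt Time step, ms (>= 0).
#' @return Updated state list.
#' @export
advance_gating <- function(params, state, v, dt) {
  if (!is.numeric(dt) || length(dt) != 1L || is.na(dt) || dt < 0) {
    stop("`dt` must be a single non-negative time step (ms)", call. = FALSE)
  }
  if (dt == 0) return(state)
  params <- as_variant_params(params)
  m_inf <- steady_state_activation(params, v)
  h_inf <- steady_state_inactivation(params, v)
  list(
    m = m_inf + (state$m - m_inf) * exp(-dt / gate_tau(params, "m", v)),
    h = h_inf + (state$h - h_inf) * exp(-dt / gate_tau(params, "h", v))
  )
}

#' Gating state at steady state for a holding potential
#'
#' @inheritParams steady_state_activation
#' @return List with `m` and `h` at their steady-state values.
#' @export
gating_steady_state <- function(params, v) {
  list(
    m = steady_state_activation(params, v),
    h = steady_state_inactivation(params, v)
  )
}
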