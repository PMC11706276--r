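# Synthetic channels and shared fixtures, built in code at test time.

# a fully characterized synthetic channel; override any field
synthetic_channel <- function(name = "SYN", peak_density = 400,
                              v_half_act = -30, k_act = 6,
                              v_half_inact = -60, k_inact = 6,
                              persistent_frac = 0, tau_rec = 1,
                              tau_inact = 1.5, e_na = 65) {
  variant_params(
    name = name, peak_density_pA_per_pF = peak_density,
    v_half_act_mV = v_half_act, k_act_mV = k_act,
    v_half_inact_mV = v_half_inact, k_inact_mV = k_inact,
    persistent_frac = persistent_frac, tau_rec_ms = tau_rec,
    tau_inact_ms = tau_inact, e_na_mV = e_na,
    non_inactivating = persistent_frac >= 0.5
  )
}

# exact Boltzmann points for fit-recovery tests
boltzmann_points <- function(v_half, k, direction, v = seq(-80, 20, by = 5)) {
  tibble::tibble(v = v, y = boltzmann_fraction(v, v_half, k, direction))
}

# decimated hybrid config for speed: identical dynamics, sparser recording
fast_dapc <- function(...) dapc_config(..., record_every = 5L)
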