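#' @useDynLib navclamp, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Reference Nav1.2 conductance: na12_fraction = 1 corresponds to this maximal
# conductance, chosen so a 0.2 fraction of N1662D yields an inward peak of
# about 80 pA under the -10 mV activation step (the five-fold-reduced
# expression scenario).
G12_REF_NS <- 7.5

#' Single-compartment axon-initial-segment model
#'
#' Leak + n^4 delayed-rectifier Kv + m^3 h s Nav1.6, plus an optional scaled
#' Nav1.2 variant conductance added by [dapc_config()]. The dynamic-clamp
#' defaults double the Kv conductance (`gkv_scale = 2`) and use 0.4 of the
#' Nav1.6 conductance (`gnav16_scale = 0.4`); the model's own Nav1.2
#' conductance is fixed at zero, as in the dynamic-clamp configuration where
#' all Nav1.2 current is external.
#'
#' Kv is a high-threshold rectifier (per-gate midpoint -5 mV) that engages at
#' the action-potential peak, deactivates slowly below ~0 mV so it carries
#' the falling phase into a deep afterhyperpolarization, and stays small at
#' the depolarized plateau produced by non-inactivating Nav1.2 current. The
#' Nav1.6 per-gate activation midpoint (-32 mV) puts the midpoint of its m^3
#' conductance curve several mV hyperpolarized to wild-type Nav1.2; its fast
#' inactivation gate h is steep and slow across the subthreshold band, and a
#' slow inactivation gate `s` (time constant 400 ms) provides
#' spike-frequency accommodation.
#'
#' @param c_m_pF Membrane capacitance, pF.
#' @param g_leak_nS,e_leak_mV Leak conductance (nS) and reversal (mV).
#' @param e_k_mV,e_na_mV Potassium and sodium reversal potentials, mV.
#' @param kv,nav16 Named lists of channel parameters (conductance, midpoints,
#'   slopes, time-constant coefficients); see defaults.
#' @param gkv_scale,gnav16_scale Dimensionless scales applied to the Kv and
#'   Nav1.6 conductances.
#' @return An object of class `ais_model`.
#' @export
ais_model <- function(c_m_pF = 20, g_leak_nS = 0.5, e_leak_mV = -65,
                      e_k_mV = -90, e_na_mV = 65,
                      kv = list(g_nS = 40, n_half = -5, n_k = 9,
                                tau_base = 0.4, tau_amp = 6),
                      nav16 = list(g_nS = 300, m_half = -32, m_k = 5,
                                   h_half = -45, h_k = 3, tau_m = 0.08,
                                   h_tau_base = 0.5, h_tau_amp = 100,
                                   s_half = -48, s_k = 3, tau_s = 400),
                      gkv_scale = 2, gnav16_scale = 0.4) {
  stopifnot(c_m_pF > 0, g_leak_nS >= 0, kv$g_nS >= 0, nav16$g_nS >= 0,
            gkv_scale >= 0, gnav16_scale >= 0)
  structure(
    list(c_m_pF = c_m_pF, g_leak_nS = g_leak_nS, e_leak_mV = e_leak_mV,
         e_k_mV = e_k_mV, e_na_mV = e_na_mV, kv = kv, nav16 = nav16,
         gkv_scale = gkv_scale, gnav16_scale = gnav16_scale),
    class = "ais_model"
  )
}

#' Dynamic action potential clamp configuration
#'
#' Pairs the AIS model with an external Nav1.2 variant current scaled by
#' `na12_fraction` (1.0 = the full wild-type-equivalent reference
#' conductance) and the step-current stimulus protocol: 1 s steps in 2 pA
#' increments between -2 and +24 pA.
#'
#' @param variant A [variant_params()] object, or `NULL` for no Nav1.2
#'   current.
#' @param na12_fraction Scale of the external Nav1.2 conductance (>= 0).
#' @param stim_start_ms,stim_dur_ms Stimulus onset and duration, ms.
#' @param stim_amplitudes_pA Step amplitudes for input-output curves.
#' @param dt_ms Integration step, ms (<= 0.02).
#' @param g12_ref_nS Reference Nav1.2 conductance at fraction 1.
#' @param record_every Keep every n-th sample in the returned traces.
#' @return An object of class `dapc_config`.
#' @export
dapc_config <- function(variant = NULL, na12_fraction = 0,
                        stim_start_ms = 200, stim_dur_ms = 1000,
                        stim_amplitudes_pA = seq(-2, 24, by = 2),
                        dt_ms = 0.02, g12_ref_nS = G12_REF_NS,
                        record_every = 1L) {
  if (!is.null(variant)) variant <- as_variant_params(variant)
  stopifnot(na12_fraction >= 0, stim_dur_ms > 0, dt_ms > 0, dt_ms <= 0.02 + 1e-12)
  structure(
    list(variant = variant, na12_fraction = na12_fraction,
         stim_start_ms = stim_start_ms, stim_dur_ms = stim_dur_ms,
         stim_amplitudes_pA = stim_amplitudes_pA, dt_ms = dt_ms,
         g12_ref_nS = g12_ref_nS, record_every = as.integer(record_every)),
    class = "dapc_config"
  )
}

hybrid_par_list <- function(ais, config) {
  v <- config$variant
  g12 <- config$na12_fraction * config$g12_ref_nS
  if (is.null(v)) {
    # inert placeholder channel (zero conductance)
    v <- variant_params("none", 1, -17.56, 6, -51.70, 6, 0, 1, 1.5, 65, FALSE)
    g12 <- 0
  }
  co <- tau_h_coefs(v)
  list(
    c_m = ais$c_m_pF, g_leak = ais$g_leak_nS, e_leak = ais$e_leak_mV,
    e_k = ais$e_k_mV, e_na = ais$e_na_mV,
    g_kv = ais$gkv_scale * ais$kv$g_nS, n_half = ais$kv$n_half,
    n_k = ais$kv$n_k, n_tau_base = ais$kv$tau_base, n_tau_amp = ais$kv$tau_amp,
    g_na16 = ais$gnav16_scale * ais$nav16$g_nS,
    m16_half = ais$nav16$m_half, m16_k = ais$nav16$m_k,
    h16_half = ais$nav16$h_half, h16_k = ais$nav16$h_k,
    tau_m16 = ais$nav16$tau_m, h16_tau_base = ais$nav16$h_tau_base,
    h16_tau_amp = ais$nav16$h_tau_amp, s16_half = ais$nav16$s_half,
    s16_k = ais$nav16$s_k, tau_s16 = ais$nav16$tau_s,
    g_na12 = g12, m12_half = v$v_half_act_mV, m12_k = v$k_act_mV,
    h12_half = v$v_half_inact_mV, h12_k = v$k_inact_mV,
    pf12 = v$persistent_frac, e_na12 = v$e_na_mV, tau_m12 = 0.1,
    th12_A = co[["A"]], th12_B = co[["B"]], th12_C = TAU_H_BELL_AMP
  )
}

#' Run one hybrid-neuron current-clamp sweep
#'
#' Integrates `c_m dV/dt = -(I_leak + I_Kv + I_Nav1.6 + I_Nav1.2) + I_stim`
#' with exponential-Euler gate updates and records the membrane potential and
#' every membrane current component. Includes 200 ms pre-stimulus settling
#' and 100 ms post-stimulus.
#'
#' @param ais An [ais_model()].
#' @param config A [dapc_config()].
#' @param stim_amplitude_pA Step amplitude, pA.
#' @return A tibble of class `dapc_sim` with columns `time_ms`, `vm_mV`,
#'   `i_leak_pA`, `i_kv_pA`, `i_nav16_pA`, `i_nav12_pA`, `i_stim_pA`;
#'   stimulus window stored in attributes.
#' @export
run_hybrid_sim <- function(ais, config, stim_amplitude_pA) {
  stopifnot(inherits(ais, "ais_model"), inherits(config, "dapc_config"))
  t_total <- config$stim_start_ms + config$stim_dur_ms + 100
  out <- run_hybrid_cpp(
    hybrid_par_list(ais, config), config$dt_ms, t_total,
    config$stim_start_ms, config$stim_dur_ms, stim_amplitude_pA,
    config$record_every
  )
  res <- as_tibble(out)
  structure(res, class = c("dapc_sim", class(res)),
            stim_start_ms = config$stim_start_ms,
            stim_dur_ms = config$stim_dur_ms,
            stim_amplitude_pA = stim_amplitude_pA,
            ais = ais, config = config)
}

#' Detect action potentials in a membrane-potential trace
#'
#' Spikes are upward 0 mV crossings separated by at least 2 ms.
#'
#' @param result A `dapc_sim` tibble, or a numeric Vm vector.
#' @param time_ms Sample times (required when `result` is a bare vector).
#' @param threshold_mV Crossing threshold (default 0 mV).
#' @param refractory_ms Minimum separation between detected spikes.
#' @return Numeric vector of spike times, ms.
#' @export
detect_spikes <- function(result, time_ms = NULL, threshold_mV = 0,
                          refractory_ms = 2) {
  if (is.data.frame(result)) {
    vm <- result$vm_mV
    time_ms <- result$time_ms
  } else {
    vm <- result
    if (is.null(time_ms)) stop("supply `time_ms` with a bare Vm vector", call. = FALSE)
  }
  up <- which(vm[-1] >= threshold_mV & vm[-length(vm)] < threshold_mV) + 1L
  if (length(up) == 0L) return(numeric(0))
  times <- time_ms[up]
  keep <- times[1]
  for (tt in times[-1]) {
    if (tt - keep[length(keep)] >= refractory_ms) keep <- c(keep, tt)
  }
  keep
}

#' Detect sustained depolarization (depolarization block)
#'
#' Sustained depolarization is declared when the mean membrane potential over
#' the final 200 ms of the stimulus exceeds the threshold and no spikes occur
#' in the final 500 ms of the stimulus — the hallmark of non-inactivating
#' Nav1.2 current clamping the membrane at a plateau. The default threshold
#' (-18 mV) lies between the two depolarized bands this model can produce:
#' passive depolarization block at the largest stimulus amplitudes parks the
#' membrane near -25 to -21 mV even with no sodium current at all, whereas a
#' plateau held open by non-inactivating Nav1.2 current sits above -15 mV.
#'
#' @param result A `dapc_sim` tibble from [run_hybrid_sim()].
#' @param threshold_mV Plateau classification threshold, mV.
#' @return One-row tibble: `sustained` (logical), `plateau_vm_mV` (mean Vm
#'   over the assessment window), `onset_ms` (first threshold crossing in
#'   the stimulus window; `NA` if never).
#' @export
detect_sustained_depolarization <- function(result, threshold_mV = -18) {
  s0 <- attr(result, "stim_start_ms")
  s1 <- s0 + attr(result, "stim_dur_ms")
  win <- result$time_ms >= s1 - 200 & result$time_ms < s1
  plateau <- mean(result$vm_mV[win])
  spikes <- detect_spikes(result)
  late_spikes <- spikes[spikes >= s1 - 500 & spikes < s1]
  sustained <- plateau > threshold_mV && length(late_spikes) == 0L
  onset <- NA_real_
  if (sustained) {
    stim <- result$time_ms >= s0 & result$time_ms < s1
    above <- which(stim & result$vm_mV > threshold_mV)
    if (length(above)) onset <- result$time_ms[above[1]]
  }
  tibble(sustained = sustained, plateau_vm_mV = plateau, onset_ms = onset)
}

#' Input-output relationship of the hybrid neuron
#'
#' Runs one sweep per stimulus amplitude and summarizes firing: the mean
#' firing frequency is the spike count during the stimulus divided by the
#' stimulus duration.
#'
#' @inheritParams run_hybrid_sim
#' @return A tibble of class `firing_summary` with columns `stim_pA`,
#'   `n_spikes`, `mean_freq_hz`, `sustained`, `plateau_vm_mV`, and a
#'   list-column `spike_times`.
#' @export
input_output_curve <- function(ais, config) {
  rows <- purrr::map(config$stim_amplitudes_pA, function(amp) {
    res <- run_hybrid_sim(ais, config, amp)
    s0 <- attr(res, "stim_start_ms"); s1 <- s0 + attr(res, "stim_dur_ms")
    spikes <- detect_spikes(res)
    spikes <- spikes[spikes >= s0 & spikes < s1]
    dep <- detect_sustained_depolarization(res)
    tibble(
      stim_pA = amp, n_spikes = length(spikes),
      mean_freq_hz = length(spikes) / (attr(res, "stim_dur_ms") / 1000),
      sustained = dep$sustained, plateau_vm_mV = dep$plateau_vm_mV,
      spike_times = list(spikes)
    )
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("firing_summary", class(out)),
            variant = if (is.null(config$variant)) NA_character_ else config$variant$name,
            na12_fraction = config$na12_fraction)
}

#' Plateau potential as a function of the Nav1.2 current fraction
#'
#' Runs the hybrid neuron at each Nav1.2 fraction and keeps the (fraction,
#' plateau Vm) pairs where sustained depolarization developed.
#'
#' @inheritParams run_hybrid_sim
#' @param variant A [variant_params()] object.
#' @param fractions Positive, sorted Nav1.2 fractions.
#' @param stim_amplitude_pA Step amplitude, pA.
#' @param config Base [dapc_config()] (variant/fraction fields are replaced).
#' @return Tibble with columns `fraction`, `plateau_vm_mV`; zero rows (with a
#'   warning) if no fraction produced sustained depolarization.
#' @export
fraction_sweep <- function(ais, variant, fractions, stim_amplitude_pA = 12,
                           config = dapc_config()) {
  stopifnot(all(fractions > 0), !is.unsorted(fractions))
  variant <- as_variant_params(variant)
  rows <- purrr::map(fractions, function(f) {
    cfg <- config
    cfg$variant <- variant
    cfg$na12_fraction <- f
    dep <- detect_sustained_depolarization(run_hybrid_sim(ais, cfg, stim_amplitude_pA))
    tibble(fraction = f, plateau_vm_mV = dep$plateau_vm_mV,
           sustained = dep$sustained)
  })
  out <- dplyr::bind_rows(rows) |> dplyr::filter(.data$sustained)
  if (nrow(out) == 0L) {
    warning("no fraction produced sustained depolarization", call. = FALSE)
  }
  out[c("fraction", "plateau_vm_mV")]
}

#' Pearson product-moment correlation
#'
#' Thin validated wrapper around [stats::cor()] used for the
#' fraction-versus-plateau association.
#'
#' @param xs,ys Numeric vectors of equal length (>= 3), neither constant.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(xs, ys) {
  if (length(xs) != length(ys) || length(xs) < 3L) {
    stop("need at least 3 paired observations", call. = FALSE)
  }
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0) {
    stop("correlation undefined for constant input", call. = FALSE)
  }
  stats::cor(xs, ys, method = "pearson")
}
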