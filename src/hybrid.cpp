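#include <Rcpp.h>
using namespace Rcpp;

// Single-compartment AIS hybrid neuron.
//
// State: V plus five gates (Nav1.2 m/h, Nav1.6 m/h, Kv n). Gates use the
// exponential-Euler update (exact at fixed V); V uses forward Euler, so the
// recorded currents satisfy c_m * (V[k+1]-V[k])/dt = i_stim - sum(I) at
// every sample to machine precision. Units: mV, ms, pA, nS, pF.

static inline double sig_rise(double v, double vh, double k) {
  return 1.0 / (1.0 + std::exp(-(v - vh) / k));
}
static inline double sig_fall(double v, double vh, double k) {
  return 1.0 / (1.0 + std::exp((v - vh) / k));
}

// [[Rcpp::export]]
List run_hybrid_cpp(List par, double dt, double t_total,
                    double stim_start, double stim_dur, double stim_amp,
                    int record_every) {
  const double c_m    = par["c_m"];
  const double g_leak = par["g_leak"], e_leak = par["e_leak"];
  const double e_k    = par["e_k"],    e_na   = par["e_na"];

  const double g_kv = par["g_kv"], n_half = par["n_half"], n_k = par["n_k"];
  const double n_tau_base = par["n_tau_base"], n_tau_amp = par["n_tau_amp"];

  const double g_na16 = par["g_na16"];
  const double m16_half = par["m16_half"], m16_k = par["m16_k"];
  const double h16_half = par["h16_half"], h16_k = par["h16_k"];
  const double tau_m16 = par["tau_m16"];
  const double h16_tau_base = par["h16_tau_base"], h16_tau_amp = par["h16_tau_amp"];
  // slow inactivation of Nav1.6: the spike-frequency adaptation variable
  const double s16_half = par["s16_half"], s16_k = par["s16_k"];
  const double tau_s16 = par["tau_s16"];

  const double g_na12 = par["g_na12"];
  const double m12_half = par["m12_half"], m12_k = par["m12_k"];
  const double h12_half = par["h12_half"], h12_k = par["h12_k"];
  const double pf12 = par["pf12"], e_na12 = par["e_na12"];
  const double tau_m12 = par["tau_m12"];
  const double th12_A = par["th12_A"], th12_B = par["th12_B"], th12_C = par["th12_C"];

  const int n_steps = (int) std::lround(t_total / dt);
  const int n_rec = n_steps / record_every + 1;

  NumericVector time(n_rec), vm(n_rec), i_leak(n_rec), i_kv(n_rec),
      i_nav16(n_rec), i_nav12(n_rec), i_stim_out(n_rec);

  // start at the passive resting potential with gates equilibrated there
  double v = e_leak;
  double n   = sig_rise(v, n_half, n_k);
  double m16 = sig_rise(v, m16_half, m16_k);
  double h16 = sig_fall(v, h16_half, h16_k);
  double s16 = sig_fall(v, s16_half, s16_k);
  double m12 = sig_rise(v, m12_half, m12_k);
  double h12 = pf12 + (1.0 - pf12) * sig_fall(v, h12_half, h12_k);

  int r = 0;
  for (int k = 0; k <= n_steps; ++k) {
    const double t = k * dt;
    const double istim =
        (t >= stim_start && t < stim_start + stim_dur) ? stim_amp : 0.0;

    const double il   = g_leak * (v - e_leak);
    const double ikv  = g_kv * n * n * n * n * (v - e_k);
    const double i16  = g_na16 * m16 * m16 * m16 * h16 * s16 * (v - e_na);
    const double i12  = g_na12 * m12 * h12 * (v - e_na12);

    if (k % record_every == 0 && r < n_rec) {
      time[r] = t; vm[r] = v;
      i_leak[r] = il; i_kv[r] = ikv; i_nav16[r] = i16; i_nav12[r] = i12;
      i_stim_out[r] = istim;
      ++r;
    }
    if (k == n_steps) break;

    // gate relaxation at the pre-step voltage
    // Kv activates fast near the spike peak but deactivates slowly below
    // ~0 mV, so it keeps conducting through the falling phase and carries
    // the membrane into a deep afterhyperpolarization
    const double n_inf   = sig_rise(v, n_half, n_k);
    const double tau_n   = n_tau_base + n_tau_amp * sig_fall(v, -10.0, 10.0);
    const double m16_inf = sig_rise(v, m16_half, m16_k);
    const double h16_inf = sig_fall(v, h16_half, h16_k);
    const double s16_inf = sig_fall(v, s16_half, s16_k);
    // slow inactivation/recovery across the subthreshold band: h16 lags the
    // slow approach to threshold (spikes can initiate), any window-current
    // plateau collapses as h16 eventually closes, and incomplete interspike
    // recovery produces spike-frequency accommodation
    const double tau_h16 = h16_tau_base +
        h16_tau_amp * sig_rise(v, -75.0, 6.0) * sig_fall(v, -30.0, 7.0);
    const double m12_inf = sig_rise(v, m12_half, m12_k);
    const double h12_inf = pf12 + (1.0 - pf12) * sig_fall(v, h12_half, h12_k);
    const double tau_h12 = th12_A + th12_B * sig_fall(v, -65.0, 10.0) +
        th12_C * sig_rise(v, -90.0, 8.0) * sig_fall(v, -50.0, 6.0);

    n   = n_inf   + (n   - n_inf)   * std::exp(-dt / tau_n);
    m16 = m16_inf + (m16 - m16_inf) * std::exp(-dt / tau_m16);
    h16 = h16_inf + (h16 - h16_inf) * std::exp(-dt / tau_h16);
    s16 = s16_inf + (s16 - s16_inf) * std::exp(-dt / tau_s16);
    m12 = m12_inf + (m12 - m12_inf) * std::exp(-dt / tau_m12);
    h12 = h12_inf + (h12 - h12_inf) * std::exp(-dt / tau_h12);

    v += dt * (istim - il - ikv - i16 - i12) / c_m;
    if (!std::isfinite(v)) stop("membrane potential became non-finite");
  }

  return List::create(
      _["time_ms"] = time, _["vm_mV"] = vm, _["i_leak_pA"] = i_leak,
      _["i_kv_pA"] = i_kv, _["i_nav16_pA"] = i_nav16,
      _["i_nav12_pA"] = i_nav12, _["i_stim_pA"] = i_stim_out);
}
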