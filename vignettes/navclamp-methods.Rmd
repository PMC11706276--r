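---
title: "Modelling NaV1.2 variant biophysics and hybrid-neuron excitability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling NaV1.2 variant biophysics and hybrid-neuron excitability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(navclamp)
```

## The problem

Missense mutations in *SCN2A* that disrupt fast inactivation of the neuronal
sodium channel NaV1.2 are associated with severe early-infantile epileptic
encephalopathy. Whole-cell voltage clamp characterizes each variant by a
handful of biophysical parameters — peak current density, the half-activation
and half-inactivation voltages of Boltzmann fits, the persistent
(non-inactivating) current as a percent of the transient peak, and the time
constant of recovery from fast inactivation — while dynamic action potential
clamp (DAPC) experiments reveal what those parameters do to the firing of a
model neuron that receives the variant current as its sodium conductance.

`navclamp` reproduces this entire workflow in silico. A single-gate
Hodgkin–Huxley model is parameterized per variant from the published
measurement table; the standard voltage-clamp protocols are simulated on it;
the same analysis pipeline a lab would run (conductance transform, Boltzmann
and single-exponential fits, the 50% non-inactivating rule) recovers the
parameters; and a conductance-based axon-initial-segment (AIS) neuron
receives the scaled variant current in simulated DAPC experiments.

## The channel model

Each variant is an ohmic conductance with one activation gate and one
inactivation gate,

$$I = g_{\max}\, m\, h\, (V - E_{Na}),$$

with steady states

$$m_\infty(V) = \frac{1}{1 + e^{-(V - V_{0.5,act})/k_{act}}}, \qquad
  h_\infty(V) = p_f + (1 - p_f)\,\frac{1}{1 + e^{(V - V_{0.5,inact})/k_{inact}}}.$$

The floor $p_f$ (`persistent_frac`) is the fraction of conductance that
never inactivates; it is the model's persistent-current mechanism and, for
the non-inactivating variants, the reason the availability curve plateaus.

A single activation gate ($m^1h^1$, not $m^3h$) is used deliberately: the
published midpoints are defined at the conductance level via the peak-G
Boltzmann fit, and a first-power gate lets the simulated peak-conductance
curve round-trip through the analysis without an exponent-induced shift.

**Kinetics.** The measurement table provides only the recovery time constant
(at the −120 mV holding potential), so the kinetic forms are package design
choices:

* $\tau_m$ = 0.1 ms, voltage-independent. Activation must be fast relative
  to inactivation so that the measured peak conductance tracks
  $m_\infty$; making $\tau_m$ voltage-dependent across the very voltage
  range used for the activation fit couples the fitted midpoint to the
  kinetics and biases it by more than the fit tolerance, so the constant
  value is used.
* $\tau_h(V) = A + B\,\sigma^-(V; -65, 10) + 5\,\sigma^+(V; -90, 8)\,\sigma^-(V; -50, 6)$ ms,
  a bell-shaped sum of sigmoids peaking near −65 mV. $A$ and $B$ are solved
  exactly (a 2×2 linear system) so that $\tau_h(-120)$ equals the variant's
  recovery time constant and $\tau_h(-10)$ equals its depolarized decay
  constant `tau_inact_ms` (default 1.5 ms for inactivating variants; slower
  for the non-inactivating group and for the slowly decaying Q1494E). The
  bell keeps mid-range $\tau_h$ below ~6 ms, so 100 ms prepulses reach
  steady state with margin.

**Slope factors.** The published table omits $k$; both slopes default to
6 mV (typical for neuronal sodium channels) and are configurable per
variant. The analysis round-trips are insensitive to the choice: the
identifiability tests sweep $k \in \{4, 9\}$ mV.

**Calibrated parameters.** Two parameters are calibrated so the *measured*
pipeline outputs match the published values: $g_{\max}$ is scaled so the
simulated peak density at −10 mV matches the published density, and, for
variants with a numeric persistent current, `persistent_frac` is solved by
bisection (`calibrate_persistent_frac()`) so that the simulated measurement
— current 40 ms into a −10 mV step divided by the transient peak — returns
the published percentage. The floor must be calibrated rather than copied
because the transient peak in the denominator is itself attenuated by the
inactivation that develops during the activation rise; copying the percent
into the floor would overshoot the measurement by up to ~1.8 percentage
points. For the non-inactivating variants the published table gives no
number; their floors (0.8 for N1662D, L1657P, Q1494A, Q1494L; 0.3 for
Q1494E; 0.15 for Q1494K) are free parameters chosen to match the described
qualitative decay behaviour, and the DAPC phenotypes hold across the
plausible range.

## Voltage-clamp simulation and analysis

Protocols are episodic: a holding potential (−120 mV) and an ordered list of
constant-voltage segments, one of which may be swept in level (IV,
availability) or duration (paired-pulse recovery). Because the command
voltage is piecewise constant, the gates evolve in closed form within each
segment — the exponential-Euler update composed over the whole segment — so
the simulated traces are exact for the model regardless of the sample
interval (0.02 ms, i.e. 50 kHz, by default). Traces are ideal, leak-free
channel currents; series-resistance and capacitive artifacts are not
emulated.

The analysis mirrors lab practice:

* **Peak detection**: most-negative sample during a step, ignoring the
  first 0.1 ms, refined by three-point quadratic interpolation so the
  measured peak does not depend on the sample grid (this is what keeps
  every fitted parameter stable to <0.1% under halving of the sample
  interval).
* **Activation**: $G = I_{peak}/(V - V_{rev})$, excluding sweeps within
  10 mV of the reversal potential, normalized to the maximum, rising
  Boltzmann fit. Fits are nonlinear least squares (Levenberg–Marquardt)
  started from the interpolated half-maximum crossing with $k = 6$;
  non-convergence and degenerate inputs are errors, never silent defaults.
* **Availability**: test-pulse current after each 100-ms prepulse,
  measured after a 1-ms blanking window. The blank (ten activation time
  constants) excludes the deactivation transient of channels left open by
  depolarized prepulses; without it the measured "peak" is contaminated by
  the instantaneous current those channels carry into the test step and
  rises again above −5 mV prepulses. Availability is normalized to the
  most-available sweep, and when the depolarized plateau exceeds 0.5% the
  plateau is subtracted and the curve renormalized before the falling fit —
  the availability of the *inactivatable* fraction. This matters well
  beyond the fully non-inactivating group: a 15% floor biases the plain fit
  by ~8 mV.
* **Persistent current**: $100 \cdot I(40\,\mathrm{ms})/I_{peak}$ on the
  −10 mV sweep; ratios ≥ 50% return the `ND` flag instead of a number.
* **Recovery**: paired 20-ms pulses to −10 mV separated by a swept interval
  at −120 mV (0.1–30 ms, log-spaced; 0.1 ms is always present because the
  inactivated-fraction method normalizes to it). Standard mode fits the
  P2/P1 ratio; inactivated-fraction mode (variants with floor ≥ 0.2) fits
  the normalized decay of the P1 − P2 difference. Both fit
  $y = 1 - A e^{-t/\tau}$ with the amplitude free: $A$ absorbs the
  non-inactivated baseline (standard mode) or the known normalization
  offset at 0.1 ms (inactivated-fraction mode); with $A$ pinned to 1 the
  fit either biases $\tau$ by up to ~15% or fails outright for variants
  with a large baseline.

## The hybrid neuron

The DAPC experiment is emulated by a single-compartment AIS model
(`ais_model()`): capacitance 20 pF, leak 0.5 nS reversing at −65 mV, an
$n^4$ delayed-rectifier Kv conductance, an $m^3 h s$ NaV1.6 conductance,
and the external NaV1.2 variant current scaled by `na12_fraction`
(`dapc_config()`). The dynamic-clamp settings double the Kv conductance and
use 0.4 of the NaV1.6 conductance; the model's own sodium conductance is
zero. Fraction 1.0 corresponds to a 7.5 nS reference conductance, set so
that a 0.2 fraction of N1662D delivers an inward peak of ~80 pA under the
activation step — the five-fold-reduced expression scenario.

The equations the original hybrid-neuron hardware implements are not
published, so this model is calibrated once against the qualitative
phenotype suite and frozen; only those qualitative phenotypes, never exact
voltages or frequencies, are claimed. The calibration logic:

* **Stimulus range fixes the passive properties.** Steps span −2 to +24 pA
  for 1 s. With 0.5 nS leak from −65 mV the passive reach at the top step
  is −17 mV, which puts both the NaV1.6 firing threshold and the NaV1.2
  plateau threshold inside the protocol's range; a stiffer or more
  hyperpolarized membrane can never engage either within ±24 pA.
* **Kv is a high-threshold rectifier** (per-gate midpoint −5 mV) that
  activates strongly only near the spike peak, deactivates slowly below
  ~0 mV so it carries the falling phase into a deep afterhyperpolarization,
  and conducts little at a −15 mV plateau — which is why a
  non-inactivating NaV1.2 current can hold such a plateau against it
  (the depressed Kv at the plateau is itself part of the observed
  phenotype).
* **NaV1.6** activates several mV hyperpolarized to wild-type NaV1.2 (m³
  conductance midpoint ≈ −24 mV), with a steep, subthreshold-slow fast
  inactivation gate: h lags the slow approach to threshold so spikes can
  initiate, and any window-current plateau collapses as h eventually
  closes. A slow inactivation gate ($\tau_s$ = 400 ms) provides
  spike-frequency accommodation — the canonical mechanism for AIS sodium
  channels — making inter-spike intervals lengthen through each sweep and
  producing the bell-shaped input–output relationship (firing declines into
  depolarization block at the largest stimuli).
* **Sustained depolarization** is declared when the mean membrane potential
  over the final 200 ms of the stimulus exceeds −18 mV with no spikes in
  the final 500 ms. The threshold sits between the two depolarized bands
  the model can produce: passive depolarization block at 20–24 pA parks the
  membrane at −25 to −21 mV with no sodium current at all, whereas a
  plateau held by non-inactivating NaV1.2 current sits above −15 mV.
* **Spikes** are upward 0 mV crossings separated by ≥2 ms.

Integration uses exponential Euler for all gates (exact at fixed voltage)
and forward Euler for the voltage at 0.02 ms, so the recorded currents
satisfy the current-balance identity
$C_m \Delta V/\Delta t = I_{stim} - \sum I$ at machine precision — that
identity is tested, as is a <0.1 mV pointwise match to the closed-form RC
response of the passive membrane and stability of spike counts and plateau
potentials under halving of the step.

## The synthetic-data generator

`cell_population()` / `sample_cells()` draw per-cell parameter sets from
independent normal distributions centred on a variant's parameters with
population SDs reconstructed as SEM·√n from the published per-variant
standard errors and cell counts (SD is not published directly). Draws are
clipped to the parameter invariants. `add_recording_noise()` adds i.i.d.
Gaussian noise per sample followed by a 10 kHz zero-phase Butterworth
low-pass, emulating band-limited amplifier noise. All randomness is
explicitly seeded; there is no unseeded path anywhere in the package.

`recovery_experiment()` closes the loop: sample cells, simulate all three
protocols per cell, add noise, run the full analysis, and report per-cell
estimates against per-cell truths. Cells whose fitted slope factors exceed
15 mV are counted as fit failures — the analogue of a lab excluding cells
whose currents are too small relative to the noise (with the published
density dispersion, a few percent of draws hit the positivity floor and
their records are pure noise).

What the generator deliberately does *not* emulate: capacitive transients,
seal leak, series-resistance error, liquid-junction offsets, correlated
cell-to-cell parameters, or non-Gaussian noise. Passing recovery tests
therefore demonstrate that the *analysis pipeline* is unbiased and robust to
band-limited noise and biological dispersion — not that it would be robust
to every artifact of real recordings.

## Problem sizes and determinism

The packaged analyses run the full published protocol geometries (28
activation sweeps, 21 prepulses, 11 recovery intervals) at 50 kHz; one
variant's complete characterization takes well under a second, and the full
twelve-variant table a few seconds. The parameter-recovery experiment in
the tests uses 20 cells at 5 pA noise; the hybrid-neuron suite simulates
14-amplitude input–output curves for seven current configurations. With
fixed seeds every result in the tests and the acceptance script is exactly
reproducible up to floating-point last digits.

## Known limitations

* Single-gate kinetics cannot reproduce state-dependent phenomena (Markov
  behaviour, slow inactivation of NaV1.2, use-dependent drug block); these
  are out of scope.
* The AIS model is a one-compartment caricature calibrated to qualitative
  phenotypes; its absolute firing rates and voltages are not predictions.
* The persistent-current floor for the non-inactivating variants is a free
  parameter constrained only by figure-level descriptions; downstream
  phenotypes were checked to be insensitive across floors of 0.5–0.9.
* Availability analysis assumes the prepulse reaches steady state; for
  channels with mid-range $\tau_h$ slower than ~20 ms the 100-ms prepulse
  would bias the fitted midpoint.

## A worked example

```{r example, eval = FALSE}
library(navclamp)

wt <- nav_variant("WT")
traces <- run_voltage_clamp(wt, protocol_activation(), recording_conditions())
activation_analysis(traces)
#> <boltzmann_fit> rising: V0.5 = -17.61 mV, k = 6.04 mV (n = 28, resid = 2.70e-03)

measure_persistent(traces)
#> # A tibble: 1 x 4
#>   variant percent ratio_pct nd
#>   <chr>     <dbl>     <dbl> <lgl>
#> 1 WT         1.06      1.06 FALSE

io <- input_output_curve(ais_model(), dapc_config(variant = nav_variant("N1662D"),
                                                  na12_fraction = 0.1))
autoplot(io)
```
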