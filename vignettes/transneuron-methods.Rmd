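---
title: "The transneuron model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The transneuron model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The physical model

A diffusive-memristor artificial neuron consists of a nanoscale gap between
the tip of a nearly formed silver filament and the counter-electrode,
bridged by one or two mobile Ag clusters, read out through a series load
resistor `R_ext` and a parallel capacitor `C`. The package integrates the
coupled Langevin system for the cluster positions `x_i`, the device
temperature `T`, and the voltage `V` across the memristor:

* position: `eta dx_i/dt = -dU/dx_i + s q V / L + sqrt(2 k_B T eta) xi_i(t)`,
  with `U` the electro-chemical confinement potential, `q` the induced
  cluster charge, `s = field_sign` the orientation of the electric pull, and
  delta-correlated unit-variance noise `xi_i` whose intensity is set by the
  instantaneous device temperature (Einstein relation, `D = 2 k_B T`);
* temperature: `dT/dt = V^2 / (C_th R(x)) - kappa (T - T0(t))` — Joule
  self-heating against Newton cooling to the bath at `T0`;
* voltage: `tau dV/dt = V_ext(t) - (1 + R_ext / R(x)) V + sqrt(D_V)
  zeta_V(t)`, the Kirchhoff current law of the RC readout with optional
  external voltage noise.

Tunnelling through the cluster(s) gives the resistance
`R(x) = R0 cosh(x / lambda)` for one cluster (`R0 = 2 R_t exp(L / 2
lambda)`) and the three-gap series sum for two clusters, which are
renumbered every step so `x1 <= x2`. Reflecting walls confine the clusters
to the gap `[-L/2, L/2]`.

A noise-free companion model replaces thermal fluctuations by deterministic
thermophoretic/thermoelectric forces. Its state is `(x, T', V, V')` where
`T'` and `V'` are thermal and electric gradients across the gap; the force
`-q_T T'` couples the cluster to the lagged thermal gradient through the
thermal charge `q_T`. This four-dimensional system is what the
fixed-point, Hopf and basin analysis in `find_fixed_points()`,
`continue_branches()`, `hysteresis_sweep()` and `basin_boundary()`
operates on.

Both models share one sign convention for the electric force
(`field_sign`, default `+1`): a positive applied voltage pulls the cluster
off its well toward the counter-electrode. The switch is exposed because
the physical sign of the induced-charge force depends on device polarity.

## Units

All quantities are dimensionless: lengths in units of the gap `L`, time in
units of the circuit constant `tau = R_ext C`, resistance in units of
`R_ext`, and `k_B = 1` energy-per-temperature so temperature is measured in
units of the confinement energy scale. Currents are therefore in units of
`V_ext / R_ext`, matching the normalisation used for reported current
traces.

## The confinement potential

`default_potential()` is a degree-six single-well polynomial with its
minimum at `-0.4 L` (the filament-tip side). Its curvature is constructed
as `U''(s) = A (s - k1)(s - k2)(s - k3)(s - k4)` with knees at
`(0.05, 0.12, 0.16, 0.27) L` from the well, giving a force profile that
rises off the well, sags over two soft shoulders, and climbs toward the
counter-electrode; `A` is set so the force maximum at the first knee is
`8 depth / L`. The two negative-curvature windows are the functional heart of
the device: combined with the voltage-divider feedback (cluster moves →
resistance falls → voltage across the gap collapses → pull weakens), each
shoulder supports an applied-voltage window in which the resting state
destabilises and the circuit becomes a relaxation oscillator. A simpler
quartic with a single shoulder was tried first and produces only one
oscillatory window and no distinct high-voltage regime; the second shoulder
is what buys the full regime sequence below. Any other shape can be
supplied through `potential_spec()`, either as polynomial coefficients or
as a tabulated `(x, U)` sample (interpolated with a natural cubic spline).

## The reference parameter set

`reference_params()` ships one calibrated operating point (a repository
artefact, not a measured device): `lambda = 0.05 L`, `R(0) = 0.0025
R_ext`, `eta = 3`, `q = 20`, `q_T = 1`, `C_th = 5`, `kappa = 0.5`,
`T0 = 0.05`, and a thermal-noise scale `k_B = 0.003` for the one-particle
model. With these values:

* the deterministic model undergoes an Andronov–Hopf bifurcation near
  `V_ext ≈ 0.72` and a second one near `V_ext ≈ 1.0`; the upper Hopf is
  subcritical, so a stable fixed point coexists with the spiking limit
  cycle over a window of roughly `[1.00, 1.05]`, and slow up/down voltage
  sweeps retrace different paths (hysteresis);
* the stochastic model spikes regularly (CV1 well below 0.5) inside the
  oscillatory window, around `V_ext ≈ 0.95`.

The two-particle variant (`reference_params(2L)`) keeps the same gap,
potential and circuit but is paired with a stronger noise scale
(`k_B = 0.01`). With two clusters the second cluster's relaxation loops
are gated by the slow diffusive wandering of the first, which opens two
additional regimes at high drive: sparse irregular spiking near
`V_ext ≈ 2.9` and intermittent bursting near `V_ext ≈ 3.3`, in which
clusters of spikes alternate with long quiet dwells in the open (low
resistance) state. `run_regimes()` therefore defaults to the two-particle
variant and the levels `(0.6, 0.95, 2.9, 3.3)`, which traverse quiescence →
regular → sparse → bursting. The pairing of each experiment with its model
variant mirrors the way measured devices are operated in different regimes
by different bias networks; both variants are first-class and any
experiment driver accepts any device.

Regime labels are rule-based and config-exposed: `quiescent` below a rate
floor (0.05 spikes per `tau`); `regular` for CV1 ≤ 0.6; `bursting` for
CV1 ≥ 1.75 together with at least 3 bursts of mean size ≥ 3 (extreme
global irregularity produced by spike clusters separated by long
inter-train intervals); `sparse` otherwise. The CV1-based burst criterion
was chosen over a burst-size cut because it separates the sparse and
bursting operating points consistently across seeds.

## Spike detection

The paper-facing statistics (ISI, CV1, CV2, PSD, burst structure) all start
from spike timestamps, and the simulator produces continuous traces, so the
detector matters. `detect_spikes()` has two modes:

* **linear** — thresholds the raw signal at
  `baseline + threshold_frac * (99.5th percentile - baseline)`; suitable
  for additive-noise fixtures with pulses on a flat baseline. Two floors
  protect against chatter: a pure-noise floor comparing the robust
  amplitude against the first-difference noise scale, and (for simulated
  traces, which carry their device parameters) an absolute floor tied to
  the device's full-on current `max(V_ext) / (R_min + R_ext)`.
* **log** — thresholds the logarithm of the conductance; a spike must
  change the conductance by at least `exp(min_swing)`-fold (default 4.5×).
  This is the mode the experiment drivers use: memristor openings are
  multiplicative events spanning decades, while the fluctuations of a
  quiescent operating point — which can have a sizeable *linear* amplitude
  when the device idles at high conductance — stay well below an e-fold.
  During calibration a purely trace-relative linear threshold systematically
  mislabelled such subthreshold chatter as spiking; the multiplicative
  criterion removes this failure mode without any per-condition tuning.

CV1 uses the population standard deviation (switchable to the sample
convention); CV2 is the trial mean of `2 |dt[n+1] - dt[n]| / (dt[n+1] +
dt[n])` over consecutive interval pairs, with the per-pair values
exposed for distribution plots.

## Numerical choices

* Euler–Maruyama with reflecting walls, Itô convention (diffusion at the
  current-step temperature). Default step `tau / 2000`: the calibrated
  device has cluster relaxation rates up to about `150 / tau`, and halving
  the step changes the firing rate by well under 5%.
* One seeded R RNG per run; identical (parameters, protocol, seed) give
  bit-identical traces.
* The deterministic model is integrated with `deSolve::ode` (`lsoda`,
  `rtol 1e-8`, `atol 1e-10`); Jacobians by central differences
  (`h = 1e-6`); Hopf points refined by bisection on the real part of the
  leading complex eigenvalue pair to `1e-6`; limit cycles detected by
  transient-discarding integration, classifying a run as spiking when the
  `x` oscillation amplitude over the last 20% exceeds `1e-3 L`.
* Fixed points are found by eliminating the (linear at frozen `x`)
  gradient/voltage subsystem analytically and scanning the residual of the
  remaining scalar equation on a 400-point grid, polishing brackets with
  `uniroot`.
* The Welch power spectral density (Hann taper, 50% overlap, mean-removed
  segments, one-sided) is implemented on `stats::fft`; total power matches
  the trace variance to within the windowing tolerance (5%).
* Two-dimensional ISI histograms use logarithmic ISI bins (bursting spans
  decades) and are column-normalised; the preferred period `t_p*` is
  interpolated with a three-point parabola around the discrete rate
  maximum.
* Convex-hull coverage uses `grDevices::chull` with `mgcv::in.out`, with
  the hull expanded by a relative `1e-9` about its centroid so boundary
  points count as covered.

## Experiment protocols

**Frequency selectivity** (`run_selectivity()`): drive
`V_ext = V_DC (1 + a cos(2 pi t / t_p))` at `V_DC = 0.95` (natural ISI
about 0.83 `tau`), periods 0.3–1.5 and amplitudes `a = 0.2, 0.4, 0.6`.
The ISI mode locks to `t_p` within about 10% over a band around the
natural period and departs outside it; the rate maximum `t_p*` shifts to
shorter periods as the amplitude grows.

**Phase comparator** (`run_phase_detector()`): voltage
`V_DC + V_AC sin(omega t)` with `V_DC = 1.35`, `V_AC = 0.12` — so the
lower half of the cycle dips into the multistability window of the
stochastic dynamics (which sits near `[1.16, 1.28]`, above the
deterministic companion's window because the thermophoretic force `q_T T'`
is absent from the stochastic skeleton) — and bath temperature
`T*(1 + a_T sin(omega t + phi))` with `T* = 0.2`, `a_T = 0.85`, common
period `20 tau` (roughly 24 natural ISIs, i.e. much slower than spiking).
When the signals are in antiphase the hot part of the cycle coincides with
the dip into the bistable window, so noise ignites the spiking state and
the cold high-voltage phase cannot extinguish it; in phase, the dip is
cold and the neuron stays quiet. The mean rate over ≥ 20 seeds is
therefore maximal at `phi = pi` and minimal at `phi = 0`.

**Energy estimate** (`estimate_energy_power()`): the heat needed to
modulate `N` silver clusters of radius `r` by `dT` once per cycle,
`E = C_Ag rho_Ag N (4/3) pi r^3 dT`, with explicit unit handling for the
radius; at the standard silver constants, ten 10-nm clusters and a 100-K
swing this is about `1.04e-14` J per cycle and about `1e-6` W at 0.1 GHz.

## Surrogate data

`generate_train()` provides seeded periodic, Poisson, gamma-renewal,
jittered-periodic, two-state bursting (Markov-modulated Poisson — the
simplest generator with controllable burst/inter-train structure) and
alternating-ISI trains; their CV statistics have closed forms (Poisson:
CV1 = CV2 = 1; gamma: CV1 = 1/sqrt(shape); alternating `a, b`:
CV2 = 2|a-b|/(a+b), approaching the supremum of 2 as the ratio diverges),
which the tests verify at `1e5` intervals. `generate_trace_with_spikes()`
embeds stereotyped Gaussian pulses at known times for detector validation,
and `generate_cv_cloud()` emulates a biological (CV1, CV2) scatter by
mixing surrogate classes whose realised statistics are recomputed, never
copied from the request. What these surrogates do *not* emulate: refractory
interactions, rate nonstationarity on slow behavioural timescales, and
measurement jitter of real recordings — passing tests on surrogates
validates the statistics pipeline, not any claim about biology.

## Problem sizes

The shipped defaults simulate 600 `tau` per regime condition over 5 seeds,
400 `tau` per selectivity condition over 4 seeds, 120 `tau` per phase over
20 seeds, a 19-point voltage grid for the bifurcation diagram, and `1e5`
intervals for the renewal-statistics checks; together the full acceptance
computation completes in a few minutes on a single core. All sizes are
arguments, so larger studies only cost time.

## Known limitations

* The reference calibration is a single documented operating point; the
  quantitative regime boundaries move with every device constant, and the
  labels are rule-based summaries of continuous behaviour.
* The deterministic cycle detector certifies existence by integration; it
  does not continue unstable periodic orbits or classify non-local
  bifurcations (no Floquet machinery).
* The two-particle model is simulated but not analysed deterministically;
  `find_fixed_points()` and friends are one-particle tools.
* External spike trains are consumed as-is; the package never recomputes
  biological CV tables from raw physiology.

```{r example}
library(transneuron)
ref <- reference_params()
protocol <- drive_protocol(voltage = list(kind = "dc", V = 0.95),
                           temperature = list(kind = "const", T0 = ref$T0))
trace <- simulate_neuron(ref$device, ref$circuit, protocol,
                         sim_config(t_max = 300, seed = 1,
                                    record_stride = 8))
train <- detect_spikes(trace, signal = "G_norm", mode = "log")
c(rate = length(train$timestamps) / train$duration,
  cv1 = cv1(train), cv2 = cv2(train))
```
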