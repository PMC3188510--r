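---
title: "The two-ring hypercolumn model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The two-ring hypercolumn model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hypercolumn)
```

## The model

The package simulates a functional hypercolumn of primary visual cortex as
two interacting ring networks (an "upper" and a "lower" layer, a schematic
input layer IV and output layer VI), each holding `n_exc` excitatory and
`n_inh` inhibitory exponential integrate-and-fire (EIF) neurons labeled by
an orientation coordinate θ ∈ [−90°, 90°). Each neuron obeys

  C dV/dt = (C/τ_m) (E_L − V + Ψ(V)) + I_syn,  Ψ(V) = Δ_T exp((V − V_T)/Δ_T),

so that above threshold the membrane potential diverges in finite time; the
divergence is the spike. Reference parameters (excitatory: τ_m = 23.3 ms,
C = 0.26 nF, E_L = −57.8 mV, V_T = −45.2 mV, Δ_T = 1.2 mV; inhibitory:
halved τ_m and C) follow dynamic I–V fits of cortical pyramidal cells and
interneurons.

**Refractoriness.** Excitatory cells use *soft* refractoriness: each spike
adds exponentially decaying offsets to the effective threshold (two
components: +22.9 mV with τ = 14.7 ms and +13.5 mV with τ = 76.2 ms), slope
factor (+10 mV, τ = 17.7 ms) and inverse time constant (+0.14 ms⁻¹,
τ = 14.3 ms). The offsets *accumulate* across spikes (decay-then-add).
Accumulation matters: with offsets that merely reset per spike the network
is bistable at low contrast and can ignite into an unphysiological runaway
state (tens of Hz at 2% contrast), because repeated firing then carries no
cumulative spike-frequency adaptation. Inhibitory cells use a hard
refractory period (default 2 ms, a conventional choice for fast-spiking
interneuron models)
during which integration is suspended.

**Synapses.** Conductance-based AMPA, NMDA and GABA classes with unit-peak
difference-of-exponentials kernels, realized as two exponential state
variables per channel (O(1) per spike). NMDA carries no voltage-dependent
magnesium block — it is a slow AMPA-like class. Peak conductances and
kinetics come from the unitary-efficacy table; the synaptic reversal
potentials are not tabulated. E_AMPA = E_NMDA = 0 mV are conventional; for
E_GABA the package ships the value recovered by its own calibration routine
(`calibrate_gaba_reversal()`), −75.1 mV, at which the two reference IPSP
amplitudes (1.13 and 1.36 mV) are reproduced within 2%. The conventional
−70 mV underestimates both by ~30% and remains available as a configuration
field. The efficacy table lists no NMDA-on-inhibitory conductance, but the
model description states that an excitatory spike evokes composite
AMPA+NMDA responses in *all* targets; the package therefore reconstructs
g(NMDA→I) = 0.21 nS at the AMPA-on-inhibitory proportion. This term is also
dynamically important: without it the slow-NMDA excitatory loop outweighs
excitation of interneurons roughly 3:1 in time-integral terms and small
scaled networks destabilize.

**Connectivity.** All pathways use the rectified tuned profile
[p0 + p1 cos 2Δθ]₊ with orientation periodicity 180°, *renormalized to
ring mean p0* and drawn as independent Bernoulli trials per ordered pair
(no autapses). The renormalization matters only for the two strongly
modulated inter-layer excitatory pathways (p1 > p0, rectification active);
it is forced by the connectivity table itself, whose mean target counts
equal p0 × (population size) for every pathway — the raw rectified
integral would give ~91 instead of ~70 targets for the lower-to-upper
excitatory-to-inhibitory pathway and ~303 instead of ~240 for
excitatory-to-excitatory. Intra-layer
inhibition dominates excitation at all angular distances. Inter-layer
excitation is strongly modulated (net coupling: excitatory near vertical
alignment, inhibitory in the surround); inter-layer inhibition is broad and
unmodulated and — per the symmetric reading of the connectivity table —
present in both directions. The coupling scale Γ ∈ [0,1] multiplies all
inter-layer peak conductances (both directions by default;
`gamma_scope = "lower_to_upper"` restricts it).

**Size scaling.** To compare networks of different sizes while preserving
the spatial mean *and* the quenched across-neuron fluctuations of the
time-averaged recurrent input, every reference probability p maps to
p(N) = p N_ref / (p N_ref + (1 − p) N), applied pointwise to the rectified
profile, and each pathway's conductance is rescaled so that (expected
in-degree) × (peak conductance) is exactly invariant. The pointwise map is
bounded by 1 by construction, which is what makes the sizes used throughout
this package (down to 500 neurons total) well defined — a common linear
factor on (p0, p1) would push the inhibitory profile's peak above 1 there.
Scaled values are always derived from stored reference values, so scaling
is idempotent and composable. External (LGN, background) synapses are
per-neuron drives and are not rescaled.

**Thalamic (LGN) input.** One Poisson-driven AMPA synapse per neuron
(g = 1 nS) with rate

  ν(θ; C) = ν₀ + ν₁ · x(C) · [cos 2(θ − θ₀)]₊,

with ν₀ = 150 Hz (the untuned dark drive, 30 afferents at the 5 Hz dark
rate) and ν₁ = 2850 Hz. The single-afferent contrast map is the
two-decade logarithmic form of the classical thalamic-drive model this
network builds on: R(C) = R_dark + (R_max − R_dark)(2 + log₁₀ C)/2,
clamped at the dark rate below 1% contrast, anchored at R(0) = 5 Hz and
R(1) = 48 Hz; x(C) = (R(C) − R_dark)/(R_max − R_dark) normalizes it to
[0, 1]. This form satisfies every constraint the drive must meet (the
two anchors, a monotone logarithmic shape, untuned at C = 0, maximal at
θ₀) and makes 2% contrast a genuinely induced condition (x ≈ 0.15)
rather than a near-dark one. The tuning broadness ε (default 1: pure
rectified cosine) interpolates toward an untuned drive at ε = 0. The lower
layer receives the same rate attenuated by a factor 2.

**Background input.** One 10 nS AMPA synapse per neuron driven by
independent Poisson events whose *shared* instantaneous rate follows an
Ornstein–Uhlenbeck process (mean 10 Hz, correlation time 10 ms). The
volatility of 1 Hz is interpreted as the stationary standard deviation of
the process, and the latent rate is advanced with the exact
discretization; negative excursions are rectified only when events are
generated, which preserves the exact-update algebra.

## Numerical scheme

* Fixed-step classical Runge–Kutta (RK4) at dt = 0.2 ms, with synaptic
  conductances and post-spike parameter offsets evaluated in closed form at
  the stage times.
* Once a membrane enters the spike-initiation zone (V above the effective
  threshold) the step is redone with 20 sub-steps; when V crosses the
  cutoff the remaining time to divergence is added analytically,
  τ_m,eff · exp(−(V − V_T,eff)/Δ_T,eff). The cutoff follows the *effective*
  parameters, max(V_cut, V_T(t) + 10 Δ_T(t)), so the exponential term
  dominates at the crossing even during post-spike relaxation; with the
  baseline parameters this reduces to the configured
  V_cut = V_T + 10 Δ_T = −33.2 mV. After a reset the remainder of the step
  is still integrated, so spike timing carries no step-size bias (verified
  against a 100×-finer reference integration to < 0.02 ms).
* Spike deliveries are aligned to step boundaries at (emission step +
  latency + 1), which guarantees no effect earlier than one latency after
  the spike at the cost of O(dt) jitter. Latencies (1.0 ms intra-layer and
  lower→upper, 3.0 ms upper→lower) are exact multiples of dt.
* Initial potentials are uniform in E_L ± 5 mV; a 500 ms warm-up precedes
  every recorded window.
* The per-step random draw schedule (one normal for the shared rate, two
  Poisson draws per neuron) never depends on network state, so paired runs
  with one spike delivery suppressed see *identical* noise realizations —
  the contract behind the single-spike perturbation experiment.

## Analysis battery

* **Tuning**: circular statistics on the orientation-doubled resultant;
  circular variance CV = 1 − |m|; circular skewness as the rate-weighted
  first sine moment about the mean direction scaled by (1 − |m|)^{3/2},
  which is zero for symmetric curves and signed by the asymmetry
  direction.
* **Contrast response**: hyperbolic-ratio (Naka–Rushton) fits via
  Levenberg–Marquardt least squares.
* **Synchrony**: χ = sqrt(Var_t[mean_i V_i] / mean_i Var_t[V_i]) over the
  upper-layer excitatory potentials, clipped at V_T by default so the
  statistic reflects sub-threshold synchrony; finite-size scaling fitted as
  χ²(N) = a + b/N.
* **LFP**: mean total synaptic input current over the upper-layer neurons
  of an 18°-wide sector (at reference size, 200 excitatory + 50 inhibitory
  cells), sampled at 5 kHz. **MUA**: three random sector cells' spike
  trains, Gaussian-smoothed (1 ms SD). Spectra and coherence use Welch
  averaging (1 s Hann segments, 50% overlap, all configurable); power is normalized to the 0 Hz power of the
  zero-contrast reference condition.
* **Pairwise correlations**: zero-lag coefficients over an 18° sector;
  spike trains are first convolved with a 10 ms square window
  (configurable) and require ≥ 100 spikes per train.
* **PSTH**: flashed stimuli (0.5 s on, 1 s off), bars normalized as
  spikes / presentations / cells. The model's sharp onset transient is not
  suppressed.

## Chaos diagnostics

Delay embedding with the reconstruction delay defaulting to the first zero
of the autocorrelation; false-nearest-neighbor fractions with the two-part
criterion (distance-ratio threshold R* = 10 plus an attractor-size test
at one series SD, both configurable); neighbor-divergence curves S(Δn) with a Theiler
window of one reconstruction delay; and an automated linear-region search
(window of ≥ 4 points, local slopes within 20% of the window mean, rise of
≥ 0.4 nats, slopes across embedding dimensions within 20%) in place of the
source's by-eye identification. The logistic map at r = 4 (λ = ln 2),
periodic signals, Ornstein–Uhlenbeck noise and phase-randomized surrogates
form the oracle battery.

## Problem sizes used by the tests

The reference network holds 10000 neurons and the model's collective
phenomena sharpen with size and recording length. The package's test
suite and acceptance script demonstrate the same constructs at desk
scale, as the package's own standard problem sizes: finite-size scaling of χ over 500/1000/2000 total
neurons with 5–10 s windows; regime contrasts, input-balance shares,
oscillation-mechanism and perturbation experiments at 2500 total neurons
with 4–10 s windows; chaos oracles on 20000–30000-sample map and noise
series. Full-scale runs remain available through the same functions.

## Known limitations

* With the package's reading of the contrast-to-rate mapping and the
  mean-preserving connection profiles, the high-contrast state is strongly
  inhibition-dominated: the interneuron rhythm (≈ 100 Hz at 2500 neurons)
  entrains sub-threshold excitatory potentials, but excitatory *firing*
  near the preferred orientation is very sparse. Downstream consequences
  at desk scale: the synchrony contrast between 95% and 2% contrast is
  compressed (χ ≈ 0.36 vs ≈ 0.24 at 2500 neurons, short of a factor-two
  separation), the feed-forward share of the input at low contrast
  slightly exceeds the 20% ceiling the model aims for (≈ 26%) because
  weak recurrent recruitment leaves the dark thalamic drive
  over-represented, and tuning/contrast-response analyses of spike output
  need long windows.
* The LFP autocorrelogram of the high-contrast state decorrelates only
  partially within three cycles at 2500 neurons (envelope ≈ 0.35 of the
  zero-lag value rather than < 0.2) and the Γ = 0 envelope is similar;
  likewise both the coupled and the uncoupled network show single-spike
  sensitivity at this size. The model's expected discrimination — chaotic
  damping with coupled layers versus coherent, perturbation-insensitive
  oscillation without — relies on sizes and recording lengths (10⁴
  neurons, minutes to hours of activity) outside the test suite's
  footprint; the functions themselves accept full-scale runs.
* No spatial geometry beyond the ring, no plasticity, no
  receptive-field/LGN front-end, no Hodgkin–Huxley option; the full
  Lyapunov spectrum and correlation-dimension estimators are out of scope.
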