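---
title: "Models and methods: pump/persistent-Na+ bursting in HN interneurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: pump/persistent-Na+ bursting in HN interneurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in `hnburst`, the
assumptions and unit conventions behind them, the numerical choices, and
the design decisions taken where the underlying biophysical description
leaves room for interpretation.

## The scientific problem

Leech heartbeat (HN) interneurons are endogenous bursters whose rhythm is
shaped by two counteracting currents that are both active throughout the
burst cycle: the persistent Na⁺ current `I_NaP`, a non-inactivating,
low-voltage-activated inward current that depolarises the cell and loads
it with Na⁺, and the Na⁺/K⁺ pump current `I_pump`, a voltage-independent
outward current activated sigmoidally by the intracellular Na⁺
concentration. Because the pump extrudes three Na⁺ ions per net
elementary charge, it is simultaneously the dominant Na⁺ efflux pathway
and a source of negative feedback on excitability. The package provides
the computational toolchain for studying this interaction: simulating a
hybrid neuron with injected `I_NaP` and `I_pump`, quantifying the
resulting bursting, classifying its regimes, and explaining the timing
of bursts geometrically from the phase plane of a reduced model.

## The full virtual hybrid neuron

`simulate_full()` integrates a single-compartment Hodgkin–Huxley-style
HN model (fast Na⁺, persistent Na⁺, three K⁺ currents, h-current, two
Ca²⁺ currents, leak) augmented with dynamic-clamp-style *injected*
persistent Na⁺ and pump currents and with native persistent Na⁺ (5 nS)
and pump (0.1 nA) components. The state is the membrane potential, the
intracellular Na⁺ concentration and fourteen gating variables. Gating
steady states are Boltzmann functions and the gating kinetics first
order with voltage-dependent time constants.

Intracellular Na⁺ evolves by bookkeeping over the Na⁺-carrying currents:
the fast and persistent (native and injected) Na⁺ currents, plus three
times the (native and injected) pump current. Na⁺ carried by the leak
and h-currents is deliberately not counted, matching the hybrid
recording convention this simulator emulates. The extracellular
concentration is constant and the Na⁺ reversal potential follows the
Nernst relation at each instant. Ca²⁺ concentrations are not modelled
(fixed Ca²⁺ reversal).

Unit system: volts, seconds, nS, nA, nF, and molar; `nS × V = nA` and
`nA / nF = V/s`, so no hidden conversion factors appear in the
equations.

### Sign and functional conventions

Two conventions are not uniquely determined by the printed model
lineage and are fixed here once:

* **Boltzmann offset sign.** All steady-state curves use
  `1/(1 + exp(A (V + B)))`, so a positive `B` places the
  half-(in)activation at the hyperpolarised potential `−B`. This is the
  convention under which every explicitly printed steady-state function
  of the reduced model (e.g. the persistent-Na⁺ activations near −40 mV)
  and the fast-Na⁺ inactivation time constant are internally consistent;
  physiologically sensible half-activations for every gate follow.
* **Generic time constant.** Where only the four parameters
  `(A, B, C, D)` of a gating time constant are known, the canonical HN
  form `τ(V) = C + D/(1 + exp(A (V + B)))` is used: `C` is the floor and
  `D` the sigmoidal range. The fast-Na⁺ inactivation keeps its own
  printed form with a `cosh` well.

### The flux-to-concentration constant

The conversion between net Na⁺-carrying current and d[Na⁺]ᵢ/dt is a
single constant `v_f` with units nA·s/M (physically, cytosolic volume ×
Faraday constant). The hybrid-recording convention expresses its
reciprocal as a multiplier (nA → mM/ms); the full model therefore uses
`v_f = 1/0.0024 ≈ 417 nA·s/M`, the reciprocal of that published
multiplier, equivalent to a ≈4.4 pl cytosolic Na⁺ reservoir.

For the reduced model the same question is subtler. Taking the
documented reservoir volume (0.0038 nl) times the Faraday constant
gives ≈367 nA·s/M; with that value every simulated and estimated burst
timing of the reduced model rescales by a common factor ≈1.39 relative
to the published characteristics of this model, while all *relative*
phase-plane quantities (inter-knee amplitude and speed ratios) are
unchanged and match to four significant figures. The timings are
reproduced when the conversion constant is the reciprocal of the volume
expressed in nl, `v_f = 1/0.0038 ≈ 263 nA·s/M`, i.e. when the published
per-volume multiplier convention is read without the Faraday factor.
Since the relative geometry pins down every other parameter exactly, the
package adopts `v_f = 1/volume` as the reduced-model default and exposes
both `volume` and `v_f` so either convention can be selected explicitly.
Only the overall time scale of the reduced model depends on this choice.

### Numerics

Both simulators integrate with `deSolve::lsoda` through compiled C
right-hand sides, with relative tolerance 1e-8 and absolute tolerances
1e-10 (V), 1e-12 (gating, concentration). Output is resampled on a
uniform grid: 5 kHz for the full model (the acquisition rate of the
recordings it emulates) and 1 kHz for the smooth reduced model. Halving
the tolerances moves measured burst durations by well under 1%
(verified in the test suite). Optional current noise for the full model
is zero-mean Gaussian, held piecewise constant over 1 ms, and seeded;
the default is noise-free, and noise-free runs are bit-reproducible.

Default initial conditions start the full model at −50 mV / 10 mM with
gating at steady state and the reduced model at −55 mV / 11 mM on the
hyperpolarised branch; analyses discard a 30 s (full) or 20 s (reduced)
transient before measuring. The experimental protocol presets hold a
−0.1 nA bias current, the holding current of the emulated recordings;
pure-model runs default to zero bias.

## The reduced two-variable model

`simulate_2d()` keeps only the membrane potential and [Na⁺]ᵢ; every
gating variable is at its voltage steady state. The current set is the
native persistent Na⁺ current, the injected persistent Na⁺ and pump
currents (with the same parameters as the hybrid experiments), the fast
Na⁺ current (which, with instantaneous gating, contributes only a
window current — the reduced model does not spike), the h-current split
3/7 Na⁺ : 4/7 K⁺ according to its −21 mV reversal, the persistent K⁺
current, and separate Na⁺ and K⁺ leaks. Its Na⁺ balance, unlike the
full model's bookkeeping, counts *all* Na⁺-carrying currents plus three
times the pump.

The model is a relaxation oscillator: the membrane potential relaxes
quickly (time scale set by `c_m`, 0.25 nF) to a stable branch of the
z-shaped V-nullcline, while [Na⁺]ᵢ drifts slowly (time scale set by
`v_f`) — rising along the depolarised branch during the burst, falling
along the hyperpolarised branch between bursts, with fast jumps at the
folds (knees). Burst duration and interburst interval are measured as
the time above and below a fixed −45 mV threshold, with crossing times
located by linear interpolation between samples.

## Phase-plane analysis

`v_nullcline()` and `na_nullcline()` locate, for each voltage on a grid
(default −75 to +5 mV, 1601 points), all concentration roots of the
total-current and total-Na⁺-flux balances by a sign-change scan over
2000 log-spaced concentrations in [0.1, 100] mM refined by bisection to
1e-12 M. `knee_points()` takes the two extrema of [Na⁺]ᵢ along the
curve, refined by a closed-form parabola through each extremal point and
its neighbours (the fit is done in centred coordinates; a least-squares
fit of raw coordinates is numerically singular at this grid spacing).
`fixed_points()` finds nullcline intersections by a sign change of the
flux balance along the V-nullcline and reports which branch each lies
on; an intersection on the middle branch is the unstable steady state
encircled by the limit cycle.

`branch_samples()` places 100 points per stable branch at the midpoints
of equal [Na⁺]ᵢ cells spanning the inter-knee range — strictly between
the knees, because the folds themselves are degenerate for the timing
estimate — and `approx_bd_ibi()` sums cell width over local |d[Na⁺]ᵢ/dt|
(a midpoint rule). The branch-mean speed reported by
`sweep_relative_change()` is the plain average of |d[Na⁺]ᵢ/dt| over the
sampled points, not a time-weighted mean. Quadrupling the number of
branch points changes the relative tables by under 0.5%, so 100 points
is well inside the converged regime.

## Burst quantification

The spike/burst pipeline mirrors standard practice for these
recordings: spikes are voltage peaks with height above 20 mV, bursts
are groups of at least five spikes delimited by interspike intervals
longer than 800 ms, undersized groups are discarded with their span
merged into the surrounding interburst interval, and a recording is
accepted only with at least eight bursts and a cycle-period coefficient
of variation below 0.25. "Height" is interpreted as topographic
prominence by default, which is robust to the slow-wave baseline riding
under the spikes; an absolute-threshold mode is available since the
original criterion could be read either way. The median spike of a
burst (used for cycle periods) is the lower median for even spike
counts. The instantaneous frequency of a burst's last spike is
undefined (its following interval is the interburst interval) and is
excluded from intraburst statistics.

The voltage envelope replaces each spike, between its bounding minima,
by the mean potential over that interval and keeps the raw potential
between bursts. Oscillation amplitudes are per-cycle peak minus
subsequent trough; "median" values are medians of the waveform backside
(peak to next trough), averaged over cycles.

## Regime classification

The two-threshold rule labels an epoch high-amplitude (HA) only when
both the envelope amplitude exceeds 20 mV and the [Na⁺]ᵢ amplitude
exceeds 1 mM. The Gaussian naive Bayes classifier is implemented from
first principles (per-class feature means and maximum-likelihood
variances, floored at 1e-9 of the largest feature variance; posteriors
by Bayes' rule with independent Gaussians) and is trained on a seeded,
stratified 35% split. Its default feature set is the pair of amplitudes
the two-threshold rule uses; spike frequency can be added. Global, not
per-experiment, thresholds are used.

## Evolutionary fitting

`evolve()` implements an elitist evolutionary strategy: each generation
evaluates a population of mutants of the current best parameter set
(Gaussian noise with standard deviation 2.5% of each parameter value —
the noise distribution is not otherwise constrained, and a uniform
option would behave similarly), keeps the best, and repeats; elitism
makes the best cost non-increasing. The cost sums, over pump-current
conditions, squared timing errors plus half the squared peak and trough
errors of the voltage and concentration waveforms, with the mixed units
(s², V², M²) summed as they stand; optional weights are provided but
default to one. Per-individual evaluations use 40 s simulations with a
15 s transient, which measures steady-state timings to well under the
mutation-induced spread. Population size and generation count default
to 16 and 100 with early stopping after 15 stagnant generations.

A caveat established while validating the fitter: near a good fit the
nine-parameter native set is not locally identifiable at small budgets.
The cost is orders of magnitude more sensitive to 2.5% changes of the
persistent-Na⁺ and leak conductances than to the h-current conductance,
and small coordinated changes of the persistent-K⁺ and persistent-Na⁺
conductances can compensate an h-current perturbation at lower cost
than restoring the true value. Parameter-recovery experiments should
therefore mutate the parameter(s) under study — the optimised subset is
an explicit argument — or use budgets far beyond the defaults; fitting
*activity* (the algorithm's purpose) is unaffected.

## What the generators emulate — and what they do not

The full-model simulator stands in for a hybrid
living-neuron-plus-dynamic-clamp preparation: it reproduces the
qualitative phenomenology (tonic spiking without injected currents
under electrode-damage leak; regular bursting with them; a
high-amplitude regime at strong injected `I_NaP`; monotone speeding of
the interburst interval and compression of the Na⁺ oscillation as the
pump maximum rises). It does not capture animal-to-animal variability,
electrode artefacts, or every quantitative trend of living neurons: in
particular, with the canonical cell parameters the low-conductance
condition (1 nS, 0.1 nA) bursts with a larger envelope and Na⁺
excursion than living low-amplitude neurons, and its burst duration
does not shorten with rising pump maximum the way living cells' and the
fitted reduced model's do. Those are properties of the canonical
parameter set, whose native conductances differ from the
experiment-fitted reduced model's; passing tests on simulated data
therefore validate the pipeline's correctness, not full quantitative
fidelity of the canonical cell to any particular living neuron.

## Problem sizes

The packaged analyses use 60–90 s simulations (20–30 s discarded) for
timing measurements, seven pump-current conditions for sweep tables,
1601-point voltage grids with 2000-point concentration scans for
nullclines, 100 points per branch for timing estimates, and
16-individual populations for fitting demonstrations. All are
comfortably inside the converged regime for the reported quantities, as
the tolerance- and resolution-doubling checks in the test suite verify.
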