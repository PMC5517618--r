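---
title: "Bursting dynamics in mouse ventricular myocytes: model, protocols, and regime analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bursting dynamics in mouse ventricular myocytes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`myoburst` simulates a detailed whole-cell model of the mouse ventricular
myocyte. The membrane carries fifteen currents: the fast Na⁺ current I~Na~
(a nine-state Markov chain with closed states C3–C1, an open state O, a fast
inactivated state IF, closed-inactivated states IC3/IC2, and two slow
inactivated states I1/I2), the L-type Ca²⁺ current I~CaL~ (a Markov chain with
voltage- and Ca²⁺-dependent inactivation), the sarcolemmal Ca²⁺ pump I~p(Ca)~,
the Na⁺/Ca²⁺ exchanger I~NaCa~, the transient outward currents I~Kto,f~ and
I~Kto,s~, the delayed rectifiers I~Kr~ (five-state Markov chain), I~Kur~,
I~Kss~ and I~Ks~, the inward rectifier I~K1~, the Na⁺/K⁺ pump I~NaK~, the
Ca²⁺-activated Cl⁻ current I~Cl,Ca~, and the background currents I~Cab~ and
I~Nab~. Ca²⁺ cycling distinguishes the bulk cytosol, a subsarcolemmal
subspace, and junctional and network SR compartments, coupled by SERCA uptake
(J~up~), RyR release (J~rel~, a four-state Markov channel), inter-SR transfer
(J~tr~), leak (J~leak~), subspace diffusion (J~xfer~) and troponin binding
(J~trpn~), with calmodulin and calsequestrin buffering in rapid-equilibrium
form and troponin as explicit state variables.

Units are ms, mV, pA/pF (currents normalized by membrane capacitance) and µM
for every concentration (Na⁺ and K⁺ included); outward current is positive
and the stimulus enters the voltage balance as a depolarizing term,
`dV/dt = -(ΣI_ion - I_stim)`. The stimulus charge is booked to the K⁺
balance, so long constant-current runs conserve total charge; over 50 s at
1 pA/pF this moves intracellular K⁺ by under 2% and the K⁺ reversal by
about half a millivolt.

The right-hand side lives twice in the package, deliberately: a compiled C
version drives the integrator, and a pure-R mirror (`compute_currents()`,
`compute_fluxes()`, `model_rhs()`) exposes every intermediate quantity for
inspection. The test suite integrates the same initial state through both and
requires agreement, which guards each transcription against the other.

## Genotype presets and the interpolation parameter

`make_parameters("wt")` is the wild-type constant set. The transgenic
TNF-α-overexpressing (heart-failure) preset `make_parameters("tg")` differs in
exactly seven parameters: the maximal SERCA uptake rate v₃ (scaling J~up~),
the Na⁺/Ca²⁺ exchanger scaling k~NaCa~, the conductances of I~Kto,f~, I~Kur~
and I~K1~, and two shape parameters of I~K1~, which is implemented in the
three-parameter form

$$ I_{K1} = G_{K1}\,\Big(\frac{K_o}{K_o+210}\Big)^{n_{K1}}
   \frac{V-E_K}{1+\exp(s_{K1}(V-E_K))}. $$

The wild-type values (G~K1~ = 0.2938 mS/µF, n~K1~ = 1, s~K1~ = 0.0896 mV⁻¹)
reduce to the classical single-parameter formulation. The TG values encode
the canonical TNF-α remodeling phenotype — SERCA uptake reduced by about a
third, Na⁺/Ca²⁺ exchange upregulated ~1.8-fold, I~Kto,f~ and I~Kur~ reduced by
35–40%, and a smaller, more strongly rectifying I~K1~. Exact remodeling
magnitudes vary between experimental reports; the preset fixes one
internally consistent choice, and the package treats it as part of the model
definition. At matched pacing the preset reproduces the qualitative failing
phenotype: higher diastolic Ca²⁺, markedly smaller Ca²⁺ transients, and
longer action potentials than wild type.

`interpolate_parameters(eps)` consolidates the seven differences into a single
coordinate ε ∈ [0, 1] (ε = 0 wild type, ε = 1 transgenic). The linear schedule
moves each flagged parameter along `p_WT + ε (p_TG - p_WT)`; at the endpoints
the presets are returned bit-identically, so ε-sweep endpoints coincide
exactly with the genotype simulations. The exponential schedule accelerates
one named parameter along `(1 - e^{-kε})/(1 - e^{-k})` with k = 5 — a
monotone, endpoint-preserving curve that reaches the failing value faster
than linearly, emulating a disease process in which one remodeling component
outpaces the others. The curvature k is a configuration knob; the specific
value is a documented stand-in, since the empirical time course of remodeling
is not known.

## Protocols and integration

Two stimulation protocols are provided. `pulsed_protocol(bcl)` is standard
pacing: 60 pA/pF pulses of 1 ms at a basic cycle length (BCL) between 30 and
150 ms. `constant_protocol(amplitude)` applies a current step of 0–1 pA/pF at
t = 20 ms and holds it, turning the myocyte into an autonomous dynamical
system. Default runs last 50 s with analysis windows of 48–50 s (pulsed) and
40–50 s (constant), long enough for the slow Na⁺/K⁺ and SR-load dynamics to
express the asymptotic regime.

Integration uses `deSolve::lsoda` with relative tolerance 10⁻⁶ and
per-variable absolute tolerances scaled to each variable's typical magnitude
(10⁻⁸ on gates and occupancies, proportionally larger on V and the ionic
pools). The integrator is restarted at every stimulus edge, so the
discontinuous pulse waveform is never stepped over; within a segment the
stimulus is constant. Output is sampled at 0.05 ms inside the analysis window
— the mouse action potential repolarizes 50% in ~4 ms, so sub-0.1 ms
resolution is needed for APD₅₀ — and at 1 ms outside it. Halving the relative
tolerance changes APD₅₀ and peak Ca²⁺ by well under 1% on a paced run (this
is a test).

`find_resting_state()` locates the quiescent fixed point by long unstimulated
relaxation (100 s, then 50-s refinement blocks until V moves by less than
10⁻³ mV per block) from the published quiescent starting point. The model has
a conserved-charge degeneracy — equilibria form a line parameterized by total
ionic content — which rules out naive Newton refinement; relaxation respects
the conservation structure and converges to scaled residuals of order 10⁻⁹.
Every simulation and every sweep point cold-starts from the resting state of
its own parameter set unless an explicit initial state is given; warm-started
continuation is possible by passing the previous run's `final_state`, but it
is off by default because orbit diagrams assembled from cold starts are
insensitive to hysteresis near subcritical transitions.

## Feature extraction and regime classification

Spikes are upward crossings of −40 mV with hysteresis: after a spike the
potential must fall below −50 mV before the next crossing counts. The reset
level sits below the depolarized silent phases of bursting (−40 to −50 mV),
so plateau ripples are not counted as spikes, and crossing times are refined
by linear interpolation. Interspike intervals (ISIs) attribute each interval
to the window containing its earlier spike. Per-beat AP amplitude is the peak
minus the preceding diastolic minimum; APD₅₀ runs from the maximal-dV/dt
upstroke (not the stimulus edge, so pulsed and constant protocols share one
definition) to 50% repolarization. On piecewise-linear synthetic waveforms
all of these agree exactly with closed-form geometry (tested).

Orbit diagrams collect local extrema of V and Ca²⁺ over the window and
cluster them in one dimension with a gap rule: 0.5 mV for voltage branches
and 2% relative for Ca²⁺ branches — coarse enough to absorb numerical jitter,
fine enough to resolve period-doubled branches. The regime classifier then
labels each window: *quiescent* (no spikes, settling below −60 mV),
*depolarized-block* (no spikes, above −55 mV), *bursting* (bimodal ISI
distribution with gap factor ≥ 3 and ≥ 2 spikes per train), *alternans*
(exactly two interleaved amplitude or ISI branches with ≥ 5 events each),
*spiking* (single ISI cluster, single amplitude branch), and *irregular* for
anything that satisfies none of these — ambiguity is reported, never forced.
The gap-factor criterion is an operational stand-in for what is a visual
judgement in published orbit diagrams; 3 cleanly separates intra-burst ISIs
(tens of ms) from inter-burst silences (hundreds of ms and up). The Ca²⁺
series gets its own label (steady / periodic / alternans / irregular) so that
voltage- and Ca²⁺-derived transitions can be compared: `ca_ap_threshold_split()`
tabulates where the two observables change regime at different control
values.

## Sweeps and thresholds

`bifurcation_sweep()` is a brute-force orbit-diagram engine: one cold-start
simulation per grid point over BCL (default 1-ms steps), constant-current
amplitude (0.01 pA/pF steps) or ε (0.02 steps), with per-point features,
regime labels, and a transition list where consecutive labels differ. Solver
failures flag the point and the sweep continues. `find_threshold()` refines a
transition by bisection down to 0.005 pA/pF (or 0.01 in ε); the caller
supplies a predicate on regime labels rather than a single target label, so
the bisection stays well defined when an intermediate regime intervenes. No
eigenvalue-based continuation is attempted: the diagrams are orbit diagrams,
and a Hopf bifurcation is reported as the regime change it produces.

## What the simulator generates, and what it does not

All data in this package are generated by the simulator itself — there is no
external data and no randomness anywhere in the pipeline (the test fixtures
are deterministic short runs plus closed-form synthetic waveforms for the
feature-extractor oracles). The model emulates an isolated, space-clamped
myocyte at the formulation's published reference temperature with fixed
extracellular concentrations. It does not represent cell-to-cell coupling,
stochastic channel gating, β-adrenergic signaling, the late Na⁺ current, or
temperature dependence; conclusions about tissue-level arrhythmia cannot be
read off these single-cell regimes.

## Numerical and design choices worth knowing

* **Stripping slow inactivation.** `strip_slow_inactivation()` removes the
  I1/I2 states and every incident edge. When a warm state is carried across
  the switch, the occupancy mass in I1/I2 is reassigned to IF, their nearest
  inactivated neighbor (configurable); fresh simulations instead start from
  the variant's own resting state, so the choice only affects warm starts.
* **Stimulus bookkeeping.** The stimulus current is carried by K⁺ in the ion
  balances. The alternative (leaving stimulus charge unassigned) introduces a
  slow K⁺ depletion of order 35 µM/s per pA/pF; at these run lengths the
  difference is sub-millivolt in E~K~.
* **Degenerate series.** A constant or monotone series has no interior
  extrema; its branch set degenerates to the end values, so steady states
  yield exactly one max and one min branch (V~max~ = V~min~), matching how
  orbit diagrams draw steady states.
* **Problem sizes.** The test suite validates properties on 1–5 s runs and
  the regime pipeline on 20–50 s runs at the default tolerances; the
  reproduction script runs the full 50-s protocol per sweep/bisection point.
  The bisection brackets span the full admissible control ranges rather than
  presuming threshold locations.

## Known limitations

The equations and constants are this package's transcription of the published
whole-cell formulation, assembled from its published description; the
transgenic preset additionally fixes remodeling magnitudes within the ranges
reported for the TNF-α phenotype. Quantities that depend sharply on the
subthreshold current balance — notably the constant-current thresholds
between quiescence, oscillatory firing and depolarized block — are sensitive
to small differences in that transcription, and the regime windows this build
produces are narrower than the published dynamics for this cell type:
sustained oscillatory firing occupies a small band of injected current
(roughly 0.71–0.78 pA/pF in WT), long-ISI single-spike oscillations take the
place of fast tonic spiking, and the depolarized state stabilizes early,
leaving no separate voltage-bursting band on the current axis, although the
stripped-scheme comparison still shows the expected larger depolarization
(block near −23 mV without slow inactivation vs −39 mV with it). The regime
machinery, the ε-interpolation, the ablation tooling and all feature
definitions are independent of these numerical sensitivities.
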