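# myoburst

Simulation and bifurcation analysis of action-potential and Ca²⁺ dynamics in
mouse ventricular myocytes, for the normal and the failing
(TNF-α-overexpressing) heart.

Heart failure remodels the ventricular myocyte: Ca²⁺ uptake into the
sarcoplasmic reticulum weakens, Na⁺/Ca²⁺ exchange is upregulated, and the
repolarizing K⁺ currents I<sub>Kto,f</sub>, I<sub>Kur</sub> and I<sub>K1</sub>
shrink. `myoburst` implements a detailed whole-cell mouse myocyte model — 15
membrane currents with Markov-chain gating of the fast Na⁺ current (9 states,
including the slow inactivated states I1/I2), the L-type Ca²⁺ current and the
RyR release channel, plus full SR Ca²⁺ cycling and buffering — together with
the analysis pipeline needed to treat the healthy-to-failing transition as a
bifurcation sequence:

* **wild-type (WT) and transgenic (TG) presets** differing in seven
  parameters (v₃, k<sub>NaCa</sub>, G<sub>Kto,f</sub>, G<sub>Kur</sub>, and
  three I<sub>K1</sub> shape parameters), and a consolidated interpolation
  parameter ε ∈ [0, 1] that morphs WT (ε = 0) into TG (ε = 1) linearly or
  with one parameter accelerated exponentially;
* **two stimulation protocols** — standard pacing (60 pA/pF, 1 ms pulses, BCL
  30–150 ms) and constant injected current (0–1 pA/pF applied at t = 20 ms),
  which turns the cell into an autonomous dynamical system;
* **feature extraction** — spike detection with hysteresis at
  V<sub>th</sub> = −40 mV, interspike intervals, per-beat AP amplitude and
  APD₅₀, orbit-diagram extrema branches for V and [Ca²⁺]ᵢ — and a regime
  classifier (quiescent / spiking / alternans / bursting / depolarized-block);
* **bifurcation sweeps** over BCL, the injected current and ε, with
  bisection-based threshold localization, voltage-vs-Ca²⁺ transition
  comparison, and the slow-inactivation ablation (`strip_slow_inactivation()`,
  the Na⁺ scheme without I1/I2) that probes the mechanism of bursting.

The model right-hand side is compiled C driven by `deSolve::lsoda` (restarted
at every stimulus edge), with a pure-R mirror of every current and flux for
inspection; the two are cross-checked in the tests. All data are generated by
the simulator — the package needs no external inputs and uses no randomness.

## Worked example

```r
library(myoburst)
wt <- make_parameters("wt")
trace <- run_simulation(wt, pulsed_protocol(bcl = 100, duration = 10,
                                            window = c(8, 10)))
feats <- extract_features(trace)
feats
#> Features over 8-10 s: regime 'spiking', 20 spikes, mean ISI 100.0 ms
#>   V branches: 1 max / 1 min; Ca regime 'periodic' (1 branches)
round(c(APD50 = mean(feats$ap$apd50), amplitude = mean(feats$ap$amplitude),
        ca_peak = max(trace$Cai), ca_diastolic = feats$ca$diastolic), 3)
#>        APD50    amplitude      ca_peak ca_diastolic
#>        3.376      112.397        0.640        0.161
```

Ten seconds of pacing at BCL 100 ms: the cell fires one action potential per
stimulus (mean interspike interval 100 ms, a single amplitude branch — regime
"spiking"), with the short mouse AP (APD₅₀ ≈ 3.4 ms, amplitude ≈ 112 mV) and
Ca²⁺ transients rising from a diastolic 0.16 µM.

A bifurcation diagram over the injected current, and the threshold where the
resting state destabilizes:

```r
dg <- bifurcation_sweep("istim", seq(0, 1, by = 0.02), base_params = wt,
                        protocol_template = constant_protocol(0))
dg$transitions                 # regime changes along the current axis
th <- find_threshold("istim", c(0, 1), tol = 0.005,
                     predicate = function(r) r != "quiescent",
                     base_params = wt,
                     protocol_template = constant_protocol(0))
```

A command-line front end for single runs and sweeps is installed at
`system.file("cli", "myoburst.R", package = "myoburst")`; traces and diagrams
are written as CSV with a JSON sidecar carrying the full protocol, solver
settings and package version (see `write_trace()` / `write_diagram()`).

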