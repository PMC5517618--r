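Package: myoburst
Title: Bursting Dynamics of Mouse Ventricular Myocyte Models of the Normal
    and Failing Heart
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates a detailed whole-cell mouse ventricular myocyte model
    (15 membrane currents with Markov-chain Na+, L-type Ca2+ and RyR gating,
    full Ca2+ cycling and buffering) for wild-type and TNF-alpha
    overexpressing (heart failure) parameter presets, with pulsed and
    constant-current stimulation protocols. Extracts action potential, Ca2+
    transient and interspike-interval features, classifies dynamical regimes
    (quiescent, spiking, alternans, bursting, depolarized block), and builds
    brute-force bifurcation diagrams over the pacing cycle length, the
    injected current, and a consolidated wild-type to failing interpolation
    parameter, including the Na+ slow-inactivation ablation that isolates the
    mechanism of bursting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
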