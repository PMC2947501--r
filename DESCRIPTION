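Package: puffmd
Title: Constant-Momentum (PUFF) Pulling Simulations and Force-Response Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the Pulsed Unconstrained Fluctuating Forces (PUFF)
    constant-momentum pulling protocol for mechanical unfolding simulations,
    together with the downstream force-spectroscopy analysis: pulse/relax
    cycling with instantaneous velocity resets between two anchor groups,
    per-pulse force bookkeeping (F = M dV), low-pass FFT smoothing of force
    traces, four-regime response classification over target-velocity sweeps,
    critical-velocity and unfolding-force estimation, and distance-plateau
    detection of unfolding intermediates. A built-in bead-spring toy engine
    (velocity-Verlet NVE, BAOAB Langevin equilibration, breakable and Morse
    bonds of known rupture force) provides synthetic systems for validation,
    and AMBER ASCII restart (rst7) readers and writers allow the controller
    to drive external molecular-dynamics engines. A harmonic-spring
    steered-MD baseline is included for contrast.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
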