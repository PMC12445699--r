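Package: nucpull
Title: Simulation and Analysis of Single-Nucleosome Magnetic-Tweezers Pulling
    Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for single-molecule force spectroscopy of nucleosomes on
    magnetic tweezers. Provides an extensible worm-like-chain model of the DNA
    tether, power-spectral-density and equipartition force calibration with a
    double-exponential magnet-position map, a stochastic generator of
    force-ramp unwrapping traces with Bell-Evans kinetics (histone-variant,
    phosphorylation, FACT-chaperone, tetrasome and dimer-deposition condition
    presets calibrated semi-analytically to target rupture-force statistics),
    and a trace-analysis pipeline that detects extension jumps, classifies
    outer/inner/full wrap ruptures, and scores nucleosome integrity across
    stretching cycles, deposition efficiency, and constant-force
    dephosphorylation events.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
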