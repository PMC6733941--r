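Package: vesolv
Title: Multi-Modal Analysis of Detergent-Induced Vesicle Solubilization
Version: 0.1.0
Authors@R:
    person("Vesolv", "Developers", email = "vesolv@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for resolving the kinetics of detergent-induced
    solubilization of sub-micron lipid vesicles into a fast swelling step and a
    slow lysis step. Provides single-vesicle FRET trajectory analysis with
    biphasic half-life fitting, spot detection and aperture photometry for
    dual-channel image stacks, ensemble FRET titration analysis with Hill-model
    fitting, fluorescence correlation spectroscopy (multi-tau correlation,
    3D-diffusion plus triplet model, focal-volume calibration, Stokes-Einstein
    sizing), and QCM-D Sauerbrey mass-phase analysis. Every stage is paired with
    a seeded synthetic-data generator embodying the forward solubilization
    mechanism, so the full pipeline is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
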