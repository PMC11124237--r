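Package: pcdpileup
Title: Photon-Counting X-Ray Detector Simulation and Small-Signal Analysis
    Under Pile-Up
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates energy-resolving photon-counting X-ray detectors at
    clinically relevant fluence rates, where pulse pile-up makes the detector
    response non-linear. Bundles elemental photon cross-section tables, a
    parametric tungsten-anode tube spectrum model with beam filtration, a
    simplified Monte-Carlo model of energy deposition in a pixel array
    (including K-fluorescence escape and Compton crosstalk), pulse-train
    synthesis with finite energy resolution, and paralyzable-like and
    non-paralyzable-like counting. The detector response is linearized around
    an operating spectrum and characterized by the perturbation point spread
    function (pPSF): the change in registered count rate per incident probe
    photon, per energy bin and pixel offset. From the pPSF the package derives
    lesion contrast and contrast-to-noise ratio per energy bin, including
    pile-up effects such as contrast cancellation and inversion.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
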