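Package: dpdecay
Title: Diastolic Pressure Decay Time Constants in a Virtual Arterial Population
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates a virtual population of arterial trees with a
    time-varying-elastance heart coupled to a reduced distributed
    (transmission-line) arterial model, extracts the diastolic pressure
    decay (DPD) time constant RC at the aortic root and the left common
    carotid artery by mono-exponential fitting over configurable diastolic
    windows, applies cuff-based waveform recalibration and additive
    Gaussian noise perturbations, and quantifies agreement between aortic
    and carotid time constants (mean absolute error, Pearson correlation,
    least-squares regression with a Wald t-test, and Bland-Altman limits
    of agreement). Includes a closed-form two-element Windkessel fixture
    generator with analytically known time constants for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
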