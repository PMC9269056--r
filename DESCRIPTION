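Package: planarpet
Title: Simulation and NEMA NU-4 Characterization of Dual-Head Planar PET
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A Monte Carlo coincidence simulator and characterization toolkit
    for organ-targeted positron emission tomography cameras built from two
    opposed planar detector heads. Models the detector geometry, point, line
    and micro hotspot (Derenzo-type) phantom sources, photon transport with
    single Compton scatter, random coincidences and paralyzable dead time;
    provides list-mode event filtering (energy window and LOR angle
    allowance), single-slice rebinning, back-projection and list-mode MLEM
    reconstruction with a median root prior; and computes the NEMA NU-4
    style performance figures: point-spread function FWHM/FWTM, axial and
    absolute sensitivity profiles, count-rate decomposition, scatter
    fraction, noise-equivalent count rate, efficiency at peak NECR and
    SUV concentration annotations.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    graphics,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
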