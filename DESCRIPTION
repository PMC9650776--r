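Package: specpair
Title: Low-Dispersion Spectrally Resolved Single-Molecule Localization
    Microscopy
Version: 0.1.0
Authors@R:
    person("specpair", "developers", email = "specpair@example.org",
           role = c("aut", "cre"))
Description: Toolkit for spectrally resolved single-molecule localization
    microscopy (sSMLM) based on a low-dispersion transmission grating placed
    close to the image plane. Simulates camera frames containing paired 0th-
    and 1st-order diffraction patterns of sparse blinking emitters, localizes
    both orders with sub-pixel maximum-likelihood Gaussian fitting, links them
    along the dispersion axis, converts the 0th-to-1st-order distance into a
    mean emission wavelength through a linear dispersion calibration,
    classifies fluorophore species from distance histograms, quantifies the
    achievable emitter density by Monte-Carlo footprint simulation, and
    assigns smFRET states in the joint (distance, width) observable space.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
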