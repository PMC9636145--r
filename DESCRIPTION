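Package: pvpix
Title: Simulation and Analysis of Photovoltaic Subretinal Implant Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models monopolar photovoltaic pixel arrays for subretinal
    stimulation: hexagonal array layouts and optical pattern projection,
    quasi-static volume-conduction fields of disk microelectrodes (with a
    finite-difference Poisson oracle), cross-resistance matrices, coupled
    nonlinear photodiode/electrode-interface circuit dynamics including
    optically preconditioned transient-return pixels, trans-cellular
    stimulation and grating-contrast metrics, and a far-field signal proxy.
    Also implements a sweep-VEP grating-acuity estimator (artifact removal,
    spectral cleaning, noise floor, log-linear fit with delta-method
    confidence intervals) together with a synthetic visually-evoked-potential
    recording generator for validating the estimator without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
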