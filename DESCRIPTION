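Package: kspaceoct
Title: K-Space Simulation and Digital Transformation of Point-Scanning OCT Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rigorous angular-spectrum (K-space) model of image formation in
    point-scanning optical coherence tomography under the single-backscattering
    (first Born) approximation, for arbitrary beam shapes without the paraxial
    approximation. Simulates complex-valued OCT volumes from point-scatterer
    scenes for Gaussian, Lorentzian, Bessel and custom aperture fields, with
    optional Zernike aberrations and measurement noise. Implements the
    generalized depth-indexed phase-and-amplitude spectral filtering function
    that transforms an acquired volume into a target form: conventional digital
    refocusing, fixed-aperture refocusing, super-refocusing towards a focal
    radius smaller than the physical focus, mutual conversion between beam
    shapes, and double-pass aberration correction, all with Tikhonov
    regularization. Includes quantitative point-spread-function metrics
    (lateral width, recovered beam radius, SNR, pair-resolution dip),
    persistence, image export and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    ggplot2,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    png,
    tiff,
    optparse
Config/testthat/edition: 3
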