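Package: sxlkit
Title: Analysis of Serial X-Ray Liquidography (SXL) Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete analysis chain for serial X-ray liquidography (SXL),
    a fixed-target pump-probe X-ray solution scattering method in which a
    40 x 30 grid of sealed microchambers is raster-scanned through the beam
    so that each chamber yields at most one laser-off/laser-on exposure pair.
    The package reduces per-chamber exposures to averaged difference
    scattering curves (azimuthal integration, Hampel despiking, high-q window
    normalisation, pair subtraction, outlier-rejecting averaging), performs
    singular value decomposition and kinetics-constrained analysis of the
    difference matrix (multi-exponential fits of right singular vectors,
    analytic sequential first-order populations, species-associated
    difference scattering extraction, rate refinement), models sample and
    photon budgets of fixed-target versus capillary measurements, and
    generates physically grounded synthetic chip datasets with known ground
    truth so the whole chain is verifiable without beamline data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    Matrix,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
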