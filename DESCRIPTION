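Package: emdiag
Title: Optical and Detector Diagnostics for Low-Voltage Electron Cryomicroscopes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Instrument-characterization toolkit for transmission electron
    cryomicroscopes operated at low accelerating voltage (around 100 keV).
    Implements contrast transfer function (CTF) evaluation with a
    temporal-coherence (chromatic) envelope computed by energy-spread-weighted
    CTF averaging, least-squares estimation of the chromatic aberration
    coefficient from defocus-versus-voltage series, spectral diagnostics of
    test-specimen micrographs (edge tapering, noise whitening, radial amplitude
    spectra, crystal lattice d-spacing prediction and peak matching), and
    counting of hybrid-pixel electron events into dose-fractionated movies with
    coincidence-loss, hot-pixel and module-gap handling. A synthetic-data
    generator emulates lattice and amorphous test micrographs, defocus series
    and sparse event streams so the whole pipeline runs without microscope
    data. Reads and writes MRC/MRCS images and plain CSV tables; results are
    tibbles that compose with the tidyverse.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
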