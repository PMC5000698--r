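Package: silkpol
Title: Backscattering Mueller Matrix Polarimetry of Fibrous Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing the wavelength-scale microstructure of
    fibrous (silk) samples from backscattering Mueller-matrix images.
    Implements frequency-distribution-histogram (FDH) central-moment
    statistics of Mueller-element images and the derived anisotropy and
    depolarization parameters c1_p1, d22_p1 and d23_p2; a dual-rotating-
    retarder Mueller polarimeter forward model with Fourier-series
    reconstruction of all 16 matrix elements; Lorenz-Mie and oblique-incidence
    infinite-cylinder single-scattering solutions; and a polarized-photon
    Monte Carlo simulator for sphere-cylinder scattering media that produces
    the backscattering Mueller images the analysis consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
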