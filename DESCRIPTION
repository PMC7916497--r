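Package: hboptics
Title: Spectral Extinction Analysis of Hemoglobin Microparticle Suspensions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward and inverse optical modelling of hemoglobin-based
    oxygen-carrier microparticles from collimated transmittance spectra.
    Builds the wavelength-dependent complex refractive index of protein
    particles from species-specific refractive-index increments (including
    Kramers-Kronig derivation of real increments from absorption spectra),
    computes single-sphere extinction cross sections by Lorenz-Mie theory,
    ensemble-averages them over a log-normal particle size distribution to
    the volume-specific extinction cross section, and inverts measured
    spectra to the mass fractions of oxy-, deoxy- and methemoglobin by
    simplex-constrained least squares.  A companion densitometry module
    solves the density-increment balance for hemoglobin versus heme-free
    protein content and the derived functional-hemoglobin summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    generics,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
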