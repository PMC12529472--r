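Package: micral
Title: Microcalibration of Infrared Hyperspectral Images by Physics-Augmented
    Calibration Transfer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Transfers quantitative calibration models built on macroscopic
    bulk FTIR spectra to the pixel spectra of infrared hyperspectral images.
    A Lorenz-Mie forward model with a Kramers-Kronig-consistent complex
    refractive index simulates the scatter distortion of microscopic pixel
    spectra; homogenized-biomass images paired with bulk spectra of the same
    samples, augmented with simulated Mie scattering, polynomial baselines
    and noise, train an attention-augmented convolutional transfer network
    that maps pixel spectra into the bulk-spectrum domain. Sequential
    application of the transfer network and a bulk-trained regression
    network yields spatially resolved chemical maps (total lipid, saturated
    and polyunsaturated fatty acid fractions, glucosamine). Includes a
    seeded synthetic-data generator, pixel quality control, leave-one-out
    cross-validation, and spectral I/O (ENVI-style and JSON hyperspectral
    cubes, CSV spectra and reference tables).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
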