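Package: miepol
Title: Mie Polarimetry and Polarized Monte Carlo Depolarization Diagrams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-sphere Mie polarimetry (Mie coefficients, angular
    functions, scattering amplitudes and the block-diagonal sphere Mueller
    matrix) together with a meridian-plane polarized Monte Carlo model of
    circularly polarized light transport in turbid slabs.  Produces
    expected-S3 depolarization curves versus the generalized size parameter
    X = diameter/wavelength, wavelength-by-diameter depolarization diagrams
    for reflection and transmission detection geometries, iso-X
    depolarization-line extraction, and wavelength-selection logic for
    discriminating particle populations by size (e.g. normal versus
    enlarged cell nuclei, red versus white blood cells).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
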