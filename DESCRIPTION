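Package: bioheatwave
Title: Non-Fourier Pennes Bioheat Modelling of Laser-Heated Tissue
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Models heat transfer in perfused biological tissue under
    localized laser heating using the Pennes bioheat equation extended with
    a finite thermal relaxation time (Cattaneo-Vernotte / telegraph-type
    hyperbolic formulation).  Provides the closed-form causal point-source
    kernel of the damped-wave bioheat equation together with its classical
    Fourier (parabolic) limit, an explicit finite-difference solver of the
    hyperbolic PDE for independent cross-validation, verification oracles
    (PDE residuals, manufactured solutions, field comparison metrics),
    skin-tissue parameter fixtures, thermal-threshold exceedance
    diagnostics, and a small command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
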