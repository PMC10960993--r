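Package: seirapls
Title: Surface-Enhanced Infrared Quantification of Drug Mixtures by PLSR
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and chemometric quantification workflow for
    surface-enhanced infrared absorption (SEIRA) spectroscopy of
    two-component drug/metabolite mixtures in a plasma background.
    Provides a Gaussian band forward model with substrate-dependent
    plasmonic gain, a multilevel partial factorial calibration design,
    region exclusion and Savitzky-Golay derivative preprocessing, a
    from-scratch NIPALS partial least squares regression with
    cross-validated latent-variable selection, and the full validation
    metric suite (RMSEC, SEC, RMSEP, bias, linearity, percent recovery,
    enhancement factors).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, signal, jsonlite
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
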