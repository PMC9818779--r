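Package: cocoanir
Title: NIR Chemometric Calibration of Cocoa Bean Quality Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Near-infrared (NIR) calibration toolkit for compositional and
    fermentation quality traits of dried cocoa beans. Provides spectral data
    containers for benchtop (850-2500 nm) and portable (900-1680 nm)
    instrument profiles, scatter corrections (SNV, SNV with detrending, MSC)
    and gap-segment derivative math treatments, partial least squares
    (NIPALS), modified PLS with per-factor residual standardization, and
    principal component regression engines, five-fold cross-validated
    evaluation with T-statistic outlier culling (SEC, SECV, R2cv, RPD and
    interpretation bands), forward interval-PLS wavelength selection, the
    arithmetic of the wet-chemistry reference assays (fermentation index,
    Kjeldahl protein, Folin-Ciocalteu total phenolics, titratable acidity,
    dry matter, shell fraction), and a seeded Beer-Lambert synthetic spectra
    generator with clean ground and scatter-degraded whole-bean modes so the
    whole pipeline is runnable and testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
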