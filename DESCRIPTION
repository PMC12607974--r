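Package: savehsi
Title: Spectrum-Aided Vision Enhancement for Endoscopic Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calibrated conversion of white-light endoscopic RGB frames into
    401-band hyperspectral reflectance cubes. Implements Macbeth colour-chart
    camera correction with a third-order polynomial response model, spectral
    reconstruction by principal component analysis plus multiple regression,
    eigenvector-based band selection, and simulated narrow-band imaging at the
    415 nm and 540 nm haemoglobin absorption bands. Ships the evaluation
    machinery used to score such pipelines (CIEDE2000 colour difference,
    SSIM/PSNR/spectral RMSE, confusion-matrix metrics with macro and
    support-weighted aggregation, two-factor ANOVA without replication), a
    reference multinomial logistic-regression classifier with moment-based
    optimisation, and seeded synthetic generators (colour charts, cameras,
    vascular phantoms, class-balanced datasets) so the whole pipeline is
    testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
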