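Package: pellspec
Title: Hyperspectral Chemometrics for Moisture Quantification in Pellet Feed
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end chemometric workflow for quantifying moisture content
    of pellet feed from near-infrared hyperspectral images (935.5-2539 nm,
    256 bands): black/white reflectance correction, sample segmentation and
    mean-spectrum extraction, Monte Carlo cross-validation (MCCV) outlier
    rejection, seven spectral preprocessing operators (FD, SD, SG, MSC, SNV,
    MC, MMN), characteristic-wavelength selection by competitive adaptive
    reweighted sampling (CARS) and the successive projections algorithm (SPA),
    partial least squares regression (SIMPLS) and random forest regression
    with cross-validated hyperparameter selection, standard chemometric
    evaluation metrics (R2, RMSE, RPD, SE, SEL), and pixel-wise moisture
    distribution mapping. Includes a synthetic NIR scene generator with
    ground truth so the full pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    randomForest,
    EBImage,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    signal
Config/testthat/edition: 3
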