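Package: pavmark
Title: Hemodynamic Marker Mapping for Peripheral Arteriovenous
    Malformations from Time-Resolved Angiography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes per-pixel and per-voxel contrast-agent transport
    markers from time-resolved angiographic image series (2D+t digital
    subtraction angiography or 3D+t contrast-enhanced time-resolved MR
    angiography): the contrast time-of-arrival (time to reach 10% of the
    local peak intensity) and the maximum dispersive wash-in slope on the
    dilution-corrected (unit-peak) time-intensity curve, together with
    their normalized variants. Provides the supporting preprocessing
    chain (background subtraction, cropping, temporal and spatial median
    filtering, global normalization, noise thresholding), temporal
    standard-deviation vessel detection, marker histograms with moment
    summaries and chi-square histogram comparison, 2D/3D colour
    renderings, a gamma-variate bolus-transport phantom simulator with
    closed-form ground truth for validation, and a reproducible pipeline
    runner.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    png,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    oro.nifti,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
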