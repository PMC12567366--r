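Package: nirband
Title: Near-Infrared Hyperspectral Band Diagnostics and Standard-to-Leaf
    Model Transfer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for probing the near-infrared hyperspectral fingerprint of
    a pure absorbing compound in a dilution series and transferring a
    standard-trained regression model to intact plant-leaf spectra.
    Implements radiometric correction of raw hyperspectral cubes, region-of-
    interest spectrum extraction, spectral preprocessing (absorbance, net
    absorbance, Savitzky-Golay derivatives, SNV, MSC), three wavelength
    selection strategies (Pearson correlation filtering, the successive
    projections algorithm, competitive adaptive reweighted sampling), partial
    least squares regression with variable-importance-in-projection scores,
    non-negative matrix factorization unmixing, a small one-dimensional
    convolutional network regressor with stratified cross-validation, and
    standard-to-leaf transfer diagnostics (similarity heatmaps, combined
    principal component analysis, median dichotomization, ROC/AUC).  A
    seeded synthetic-data generator emulating an eight-level dilution series
    and eight leaf cultivars makes every stage testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    signal,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    pROC,
    mixOmics,
    withr
Config/testthat/edition: 3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'wavelength-grid.R'
    'spectra-table.R'
    'generator.R'
    'hypercube.R'
    'envi-io.R'
    'preprocessing.R'
    'band-selection.R'
    'pls.R'
    'decompose.R'
    'metrics.R'
    'cnn.R'
    'transfer.R'
    'pipeline.R'
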