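Package: frostspec
Title: Hyperspectral Assessment of Low-Temperature Stress in Tea Plants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Chemometric pipeline for quantifying freezing injury in tea
    (Camellia sinensis) leaves from visible/near-infrared reflectance
    spectra. Builds a composite Low Temperature Response Index (LTRI) from
    six physiological markers (SPAD chlorophyll, soluble sugar,
    malondialdehyde and the antioxidant enzymes CAT, POD, SOD) via a
    principal-component coefficient chain; preprocesses leaf spectra
    (black/white reflectance correction, ROI extraction, multiplicative
    scatter correction, Savitzky-Golay smoothing, first derivative);
    selects informative wavelengths by SPA, CARS and UVE; and fits a grid
    of regression models (native NIPALS PLS, SVM, random forest,
    back-propagation network, 1-D CNN, LSTM) evaluated by R2, RMSE and RPD
    under repeated cross-validation. Includes a synthetic-data generator
    that emulates the two-cultivar, six-treatment cold-stress design for
    property-based testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    e1071,
    randomForest,
    nnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
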