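Package: tmsri
Title: Retention Index Prediction for Trimethylsilyl Derivatives of Metabolites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Machine-learning retention index (RI) prediction for trimethylsilyl
    (TMS) derivatives of metabolites in gas chromatography-mass spectrometry.
    Fits interchangeable fingerprint-based regression backends (linear and
    polynomial support vector regression, random forest, mean baseline) under a
    repeated random-split protocol, provides the TMS-counterpart linear shift
    baseline, calibrates similarity-conditioned empirical error probabilities
    (CPF), and evaluates candidate ranking and filtering for chemical- and
    electron-ionization identification scenarios. Includes a synthetic
    derivative-library generator with known ground truth for end-to-end testing,
    plus CSV/TSV/SDF library and MSP spectrum input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ChemmineOB,
    ChemmineR,
    e1071,
    randomForest,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
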