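Package: fliopipe
Title: FLIO and OCT-A Cohort Analysis with ETDRS Sectorization and SVM Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for fluorescence lifetime imaging ophthalmoscopy
    (FLIO) and OCT angiography (OCT-A) cohort studies of retinal metabolic
    change, built around a smoker versus non-smoker classification task.
    Provides ETDRS-grid sectorization of 256x256 mean-lifetime and intensity
    matrices into 36 named features, pooled-variance t-test feature ranking,
    grouped stratified repeated 5-fold cross-validation of an RBF-kernel
    support vector machine with confusion-matrix aggregation, OCT-A image
    encodings (value histograms, circular-grid sectorization, local
    box-counting fractal dimension density maps), PCA reduction and exact
    t-SNE cohort embeddings, and a synthetic cohort generator that emulates
    the statistical design of the clinical study so every stage is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    e1071,
    EBImage,
    png,
    jsonlite,
    yaml,
    rlang,
    withr
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    cluster
Config/testthat/edition: 3
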