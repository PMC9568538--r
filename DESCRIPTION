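Package: painstrips
Title: Pain Intensity Classification from Facial Images via Horizontal
    Strip Deep Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Facial pain-intensity classification pipeline built from
    interchangeable stages. FACS action-unit intensities are converted to
    Prkachin-Solomon Pain Intensity (PSPI) scores and grouped into four
    ordinal pain classes with seeded under-sampling for class balance.
    Pre-cropped face images are resized to 224x224 and decomposed into 21
    dynamic-sized horizontal strips ("shutter blinds") at four scales; a
    pluggable backbone extracts a fixed-length deep-feature vector per
    strip and per whole face (22 x 1000 = 22,000 features in the reference
    configuration). Features are min-max normalized, ranked by a
    feature-selection variant of neighborhood component analysis, and
    pruned by iterative prefix selection (INCA). A k = 1 Manhattan-distance
    nearest-neighbor classifier under stratified ten-fold cross-validation
    yields pooled confusion matrices and a full multiclass metric suite:
    accuracy, unweighted average recall and precision, macro-F1, Gorodkin
    multiclass Matthews correlation, Cohen's kappa and the geometric mean
    of class recalls. Seeded synthetic fixtures (action-unit tables and
    band-structured face-like images) make every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    EBImage,
    SummarizedExperiment,
    S4Vectors,
    jsonlite,
    withr,
    optparse,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
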