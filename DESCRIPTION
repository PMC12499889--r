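Package: voltmatrix
Title: Voltage-Matrix Profiling of Solid-State Nanopore Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis toolkit for voltage-matrix profiling of
    solid-state nanopore recordings. Generates seeded synthetic ionic-current
    traces with voltage-dependent Poisson capture, run-level baseline offsets
    and class-specific translocation event shapes; detects translocation
    events with a two-threshold (Schmitt-trigger) detector over a moving-median
    baseline; extracts event-intrinsic and baseline-dependent feature sets;
    builds train-voltage by test-voltage AUC classification matrices with
    Random Forest or SVM classifiers; and estimates mixture composition from
    classifier score histograms via two-component Gaussian fitting, optimized
    decision boundaries and capture-frequency correction.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    randomForest,
    e1071
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
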