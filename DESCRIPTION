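Package: mpfast
Title: MP-FAST Bragg-Peak Detection and Hit Finding for Serial Crystallography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data reduction for serial (femtosecond) crystallography frame
    streams. Implements pixel-wise rolling-median background and detector
    artefact subtraction from a FIFO buffer of recent miss frames, the
    MP-FAST modified FAST key-point detector for Bragg-peak apices
    (minimum-intensity threshold, four-cardinal-pixel high-speed test with a
    three-of-four rule, eight-neighbour apex refinement and duplicate
    suppression), a fixed-length region-count image descriptor, and hit/miss
    classification with MLP, SVM, random-forest and Gaussian naive-Bayes
    models, together with a labelled synthetic-frame generator and a
    command-line pipeline for simulate/detect/featurize/train/classify
    workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    ranger,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
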