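Package: hemobleed
Title: Detection of Postoperative Major Bleeding Events in Chinese Electronic Medical Records
Version: 1.0.0
Authors@R:
    person("hemobleed", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Tools for phenotyping ISTH-defined major bleeding events in
    postoperative tumor-resection hospitalizations from Chinese electronic
    medical record free text plus semi-structured laboratory and transfusion
    records. Implements a 270-dimensional binary feature scheme (manually
    curated bleeding regular expressions, frequency-selected segmentation
    tokens, and a quantitative ISTH adjudication feature), three classifiers
    (logistic regression and a 1-D convolutional network trained with sigmoid
    focal cross-entropy and Adam, plus k-nearest neighbours), a full
    confusion-matrix/ROC evaluation suite with printed-metric reconstruction
    utilities, and a seeded synthetic note-corpus generator so the pipeline is
    testable end to end without access to protected source data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    stringi,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
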