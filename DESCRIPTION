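Package: s5m
Title: Statistically Significant Submodular Subset Shapelet Mining
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines short time-series subsequences (shapelets) that are both
    statistically significantly associated with a binary phenotype and
    structurally representative of the data. Significance is assessed with a
    chi-squared test over all distance thresholds and corrected for multiple
    testing with Tarone's procedure; representativeness is decided by
    maximizing a submodular facility-location / sum-redundancy mixture
    objective with a single-pass stochastic optimizer (bidirectional
    iterative greedy, BIG) that interleaves with the testability bookkeeping
    so non-representative shapelets never inflate the correction factor.
    Includes the planted-prototype simulation designs, retrieval metrics
    (precision, recall, F1, minimum similarity), greedy and bidirectional
    greedy comparison optimizers, and four two-stage comparison pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
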