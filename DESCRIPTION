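Package: toothset
Title: Multi-View Image-Set Classification with Attention Fusion and
    Consensus Label Refinement
Version: 0.1.0
Authors@R:
    person("Morgan", "Carter", email = "m.carter@example.org",
           role = c("aut", "cre"))
Description: A toolkit for classifying objects photographed from several
    standardized directions, built around isolated-tooth identification
    from six-view photograph sets. Provides a shared-weight convolutional
    view encoder with a transformer-style attention module that fuses the
    per-view features into a single set-level prediction; a weighted-voting
    consensus procedure that turns multiple rater annotations into
    pseudo-ground-truth labels or removes ambiguous specimens; a
    hierarchical evaluation suite (top-k accuracy, confusion matrices,
    per-class sensitivity/specificity, one-vs-rest ROC/AUC, Cohen's and
    Fleiss' kappa) across nested label granularities; and a procedural
    synthetic multi-view image generator with simulated annotators for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
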