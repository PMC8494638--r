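Package: patchmodal
Title: Multimodal Patch-Seq Analysis of Cortical Neurons
Version: 0.1.0
Authors@R:
    person("Patch", "Modal", email = "maintainer@patchmodal.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for triple-modality Patch-seq analysis of
    cortical neurons: intrinsic electrophysiology feature extraction from
    current-clamp sweeps (spike detection, subthreshold and suprathreshold
    features, sweep quality control), neuronal morphometry from SWC
    reconstructions with laminar alignment and depth histograms,
    transcriptomic cell-type assignment by correlation to reference cluster
    centroids with marker-gene (beta) scoring and cluster-structure
    statistics, laminar histology profiling with nadir-based boundary
    detection, and cross-modal group and depth-gradient statistics with
    robust inference and FDR control. Ships a synthetic-data module that
    generates all four input kinds with known ground truth so every stage is
    testable without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
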