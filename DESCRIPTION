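Package: popcode
Title: Population Coding Analysis of Multi-Channel Hippocampal Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the population code of simultaneously
    recorded neurons: spike sorting from multi-channel extracellular traces
    (mean-signal referencing, amplitude-threshold detection, PCA plus
    Gaussian-mixture clustering, inter-spike-interval quality control),
    wheel-encoder behaviour decoding and running/stationary epoch
    segmentation, behaviour-conditioned pairwise correlations with
    firing-rate-matched shuffle nulls, Shannon entropy of binary population
    spike patterns over subsampled ensembles, and exact independent and
    pairwise maximum-entropy (Ising) models of population activity with
    Kullback-Leibler model evaluation. A synthetic-data module generates
    raw traces, spike trains, binary rasters and behaviour with known
    ground truth so every stage of the pipeline can be validated.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    mclust,
    signal,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
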