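Package: caimnet
Title: Functional Organization Analysis for Calcium Imaging of Clustered Neuronal Cultures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of fluorescence calcium-imaging recordings of
    clustered neuronal cultures: onset detection from per-ROI traces, grouping
    of onsets into firing sequences, drift-corrected firing-rate and
    sequence-rate statistics, surrogate-normalized directed functional
    connectivity, Jaccard-similarity community detection with Variation of
    Information threshold selection, and weighted-directed network topology
    descriptors. Includes a synthetic generator of clustered-culture activity
    with configurable perturbations (cluster silencing, inter-community
    weakening, activity boosting) for validation and power analysis, and a
    network-burst mode for homogeneous cultures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    igraph,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
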