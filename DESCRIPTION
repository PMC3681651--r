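Package: SpikeNets
Title: Compression-Based Functional Connectivity and Small-World Analysis of Neuronal Recordings
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers functional connectivity graphs from simultaneous
    multi-unit spike recordings and local field potentials. Spike-train
    similarity is measured by the Normalized Compression Similarity, a
    variable-order Markov (PPM) compression statistic able to detect
    arbitrarily lagged shared firing patterns; LFP channel coupling is
    measured by Hilbert-phase synchrony. Windowed weighted adjacencies are
    binarized and screened by admissibility rules, then characterized with
    small-world statistics (clustering coefficient, characteristic path
    length, degree-preserving randomized and latticized null models, the S
    and omega small-worldness indices), betweenness centrality and modularity
    communities. A generative cell-assembly simulator with embedded
    Watts-Strogatz subnetworks firing in betweenness rank order, plus
    synthetic benchmark generators (drifting shared patterns, independent
    train pairs, phase-coupled signal pairs), support validation without any
    recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    signal,
    knitr
Config/testthat/edition: 3
biocViews: Software, Network, GraphAndNetwork, Electrophysiology, TimeCourse
RoxygenNote: 7.3.3
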