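Package: mrcpbench
Title: Factorial Benchmarking of Movement-Related Cortical Potential Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for benchmarking single-trial detection of movement-related
    cortical potentials (MRCPs) in self-paced electroencephalography (EEG).
    Provides a synthetic session generator with known ground truth (slow
    pre-movement negativity focused near Cz, pink-noise background, EMG burst
    annotations), causal Butterworth band decomposition and 2-s epoch
    extraction, five spatial representations (none, surface Laplacian, ICA,
    CSP, PCA), six detectors (shrinkage LDA, grid-searched SVM, 1-NN with
    Euclidean and band-constrained DTW distances, matched filter, and
    DBA-template matching), F1-scored execution of the full band x spatial x
    detector factorial grid, and repeated-measures ANOVA with
    Greenhouse-Geisser correction, Bonferroni post hoc tests, and estimated
    marginal means.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    e1071,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
RoxygenNote: 7.3.3
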