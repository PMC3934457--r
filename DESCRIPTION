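Package: PulseTWED
Title: Elastic Kernel Classification of Arterial Pulse Waveforms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classification of single-period arterial pulse waveforms with
    elastic distance kernels. Implements the time warp edit distance (TWED)
    and edit distance with real penalty (ERP) metrics as iterative dynamic
    programs, Gaussian elastic kernels (GTWED, GERP) with Gram-matrix
    construction, caching and positive-definiteness diagnostics, a support
    vector machine trained on precomputed Gram matrices with one-vs-one
    multiclass voting, 1-nearest-neighbour baselines, a wavelet preprocessing
    chain from raw pressure records to normalized 150-sample periods
    (denoising, baseline-drift removal, onset detection, period selection),
    a seeded generator of synthetic five-pattern pulse data, and a nested
    10-fold cross-validation protocol with grid search over the kernel and
    SVM hyperparameters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    Rcpp,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
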