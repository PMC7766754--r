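Package: squigglesim
Title: Simulation of Nanopore Sequencing Current Signals with a Trainable
    BiGRU Filter
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates Oxford Nanopore raw current signals ("squiggles")
    from nucleotide sequences. A 6-mer pore model converts a sequence into
    its expected current levels, repeat times drawn from a mixture-alpha
    dwell model expand the levels into a square-wave ground-truth signal,
    and a trainable three-layer bidirectional GRU network (fit with
    log-cosh loss and Adam) replaces the classical windowed-sinc low-pass
    filter before Gaussian noise is added. Includes dynamic-time-warping
    based signal labeling for building supervised training pairs, DTW and
    continuous-wavelet-spectrum evaluation of simulated against real
    signals, and a fully synthetic data generator so the whole pipeline
    runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
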