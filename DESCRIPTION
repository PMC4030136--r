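Package: prestim
Title: Pre-Stimulus EEG Microstates, Distributed Sources, and Alpha Phase
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-trial analysis of pre-stimulus EEG in epoched, multichannel
    recordings. Extracts the topographic map at the global-field-power peak
    closest to stimulus onset in each trial, clusters these maps with a
    polarity-invariant (modified spatial) k-means, selects the number of
    microstate classes by the cross-validation criterion, back-fits templates
    to trials and contrasts global explained variance between conditions.
    Companion stages provide zero-phase Butterworth band-pass filtering,
    reference transforms, Perrin spherical-spline channel interpolation, an
    analytic three-shell spherical-head lead field with a LAURA-style
    regularized distributed inverse and solution-point-wise statistical
    mapping under FDR control, and Blackman-windowed DFT alpha power/phase
    analysis with circular statistics (Watson-Williams tests) under multiple
    reference schemes. A synthetic-data generator with full ground truth
    drives validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    Matrix,
    signal,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
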