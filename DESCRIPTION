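Package: pwcnet
Title: Few-Shot Pulse Wave Contour Classification with Multi-Scale Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies single-channel pulse wave contours (photoplethysmography
    or continuous non-invasive blood pressure recordings) into two morphology
    classes under few-shot conditions. Provides an empirical mode decomposition
    (EMD) front end with endpoint-anchored spline envelopes for denoising, a
    Pearson-correlation retention gate, trough-based beat segmentation and
    fixed-length beat resampling; a small-parameter recurrent unit (a single
    forgetting gate with a convex state update, half the parameters of an LSTM
    cell) assembled into a bidirectional layer with Bernoulli-mask coupling;
    parallel one-dimensional (within-beat) and two-dimensional (across-beat
    rhythm) convolutional feature branches with a softmax inference head; Adam
    training with analytic backpropagation; the five standard confusion-matrix
    metrics; and a synthetic pulse-waveform generator so the whole stack is
    trainable and testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    generics,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
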