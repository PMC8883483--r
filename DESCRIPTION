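Package: wmrnn
Title: Leaky Recurrent Networks for Spatial Working-Memory Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trains continuous-time leaky recurrent neural networks on
    oculomotor delayed-response tasks (with distractor and anti-response
    variants) by backpropagation through time, decodes saccadic endpoints
    with a population-vector readout, and provides the unit-level analyses
    used to diagnose bump-attractor-like working-memory maintenance:
    delay-unit selection, tuning rotation, behavior-rate correlation,
    Fano-factor variability, correct-versus-error contrasts, and
    weight-structure statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
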