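Package: aemid
Title: Acoustic Emission Analysis for Medical Interventional Device Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for monitoring medical interventional devices (biopsy
    needles, guide wires) from audio recorded at the proximal end of the
    device. Implements sliding-window time-varying autoregressive (TV-AR)
    modelling of the acoustic emission, pole decomposition with residue-based
    spectral powers, tracking of the maximal-energy pole (TV-MEP), CUSUM
    detection of needle tissue entry and exit, and a 16-feature support
    vector machine classifier separating guide-wire vessel perforation from
    friction and bump artefacts. Includes wavelet-scale and Butterworth
    band-pass preprocessing, WAV input/output, and a synthetic signal
    generator with ground-truth annotations so that every pipeline stage can
    be exercised without access to recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
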