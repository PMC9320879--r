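Package: gazecoder
Title: Automated Gaze Coding and Looking-While-Listening Analysis for
    Infant Video Sessions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Frame-by-frame classification of infant gaze direction
    (left, right, away) from low-resolution face video using a
    multi-frame convolutional network over stacks of five face crops
    taken from alternating frames of a rolling ten-frame window.
    Includes physical-plausibility post-processing of the predicted
    label timeline (no direct left/right flips), frame-level agreement
    evaluation against human coders (confusion matrices, support-weighted
    F1 aggregated across videos), and the downstream looking-while-listening
    trial analysis (critical-window accuracy, trial and participant
    exclusion rules, one-sample tests versus chance, and a 2x2
    fully-within-subjects ANOVA with partial eta squared). A synthetic
    session simulator with semi-Markov gaze dynamics and a parametric
    face renderer provides fully annotated sessions with known ground
    truth so the entire pipeline can be trained and validated at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
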