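Package: posegait
Title: Walking-Pattern Classification from Body-Worn Tracker Pose Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
                  role = c("aut", "cre"))
Description: Tools for assessing gait instability from the 6-DoF pose stream
    of a chest-mounted visual-inertial tracker. Converts absolute camera
    poses into previous-frame-relative representations, clamps tracking
    glitches, cuts sliding windows, and classifies walking patterns
    (normal, medial-lateral instability, anterior-posterior instability,
    and combined instability) with a lightweight CNN-Transformer sequence
    model, including a subject-specific fine-tuning protocol, macro-averaged
    evaluation metrics, per-frame prediction timelines, and false-alert
    smoothing. A synthetic gait simulator generates labeled pose sequences
    emulating short straight-line walks so the full pipeline can be
    developed and benchmarked without access to tracker hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: Rcpp, jsonlite, yaml, stats, utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
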