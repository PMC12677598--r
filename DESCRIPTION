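Package: ecogpipe
Title: Motor Decoding Pipeline for High-Density Micro-Electrocorticography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for motor decoding from
    high-density micro-electrocorticography (uECoG) grid recordings.
    Generates synthetic multichannel cortical sessions with known kinematic
    tuning, extracts z-scored high-gamma (70-150 Hz) band power features in
    100 ms bins, decodes three-dimensional kinematics with a
    position-velocity Kalman filter, scores performance with Pearson
    correlation, signal-to-noise ratio and bit-rate statistics, runs
    closed-loop cursor tasks with assisted control, and reproduces
    electrode-density, cortical-coverage and channel-contribution
    subsampling experiments based on random-forest Gini importance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    randomForest,
    Rcpp,
    signal,
    stats,
    utils,
    graphics,
    withr
LinkingTo: Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
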