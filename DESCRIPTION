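Package: maatkit
Title: Processing and Analysis of Mobile Approach-Avoidance Task Sensor Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the mobile Approach-Avoidance Task (mAAT), in which
    participants pull a phone towards their face or push it away in response
    to images while the phone's inertial sensors record the movement. The
    package turns raw timestamped accelerometer traces into motion-onset
    reaction times and a movement-distance measure via double integration,
    applies trial- and participant-level validity rules, aggregates
    participant-by-category-by-direction cells, and reproduces the standard
    statistical layer (two-by-two repeated-measures ANOVAs, Wilcoxon
    signed-rank tests, Pearson correlations). A minimum-jerk motion simulator
    generates whole synthetic experiments with known ground truth so every
    pipeline stage can be verified end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
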