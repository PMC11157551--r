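Package: emgavatar
Title: EMG-Driven Avatar Dynamics and Perceptual Rating Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing an electromyography-driven
    virtual-arm (avatar) control loop. Converts two-channel surface EMG into
    percent-MVC activations and the agonist-antagonist (AA) ratio motor
    command, simulates the neuromusculoskeletal (NMSS) transfer-function
    cascade (two second-order sections plus dead time) that maps the AA-ratio
    deviation onto an elbow-joint angle at simulation and render rates, and
    characterises each parameter setting's response (lag, DC gain, overshoot),
    including the negative-delay regime reached at high natural angular
    frequency. Ships seeded generators for synthetic EMG, randomized
    experimental protocols and virtual-participant questionnaire ratings, and
    implements the perceptual-rating analysis: paired comparisons with
    Holm-Bonferroni adjustment, effect sizes from the t statistic with
    categorical labels, and peak-distribution histograms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    deSolve,
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
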