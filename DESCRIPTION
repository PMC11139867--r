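Package: fluctkin
Title: Kinematic and 1/f-Fluctuation Analysis of Surgical Instrument Tip
    Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for objective surgical-skill assessment from instrument
    tip coordinate time series. Computes per-video kinematic indices
    (travel distance, velocity, acceleration, jerk, tip occurrence rate,
    distance-per-second distribution and hovering ratio), estimates the
    1/f^beta spectral fluctuation exponent of the step-length series via
    windowed FFT periodograms and a log-log least-squares fit, evaluates
    detector masks (true positive rate, false positive rate, Dice,
    tip-hit rule), and performs cohort-level discrimination statistics
    (Mann-Whitney U, Spearman correlation, ROC with Youden cutoff,
    Monte-Carlo power). Includes a seeded synthetic trajectory simulator
    with tunable spectral exponent, hover episodes and visibility gaps,
    so the whole pipeline is testable without video data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    tools,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
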