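Package: emgreward
Title: Reward Modulation of Sensorimotor Feedback Responses from Surface EMG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how monetary reward modulates sensorimotor
    feedback responses measured with surface electromyography (EMG).
    Implements five robot-based task designs (In-Out Target, Target
    Selection, Cursor Jump, Target Jump, and Proprioception-cued Reaction
    Time) with their factorial trial schedules and monetary-return
    functions; a synthetic-EMG generator with known ground truth for
    validating every analysis stage; the EMG conditioning chain
    (band-pass filtering, full-wave rectification, calibration-based
    normalization, event alignment, trial-baseline statistics);
    ROC-based response-latency estimation with segmented-regression
    onset detection; windowed trapezoid-integral feedback gains and
    reward log-ratios; reaction-time detection from EMG threshold
    crossings; and paired Wilcoxon signed-rank statistics with a
    common-language effect size.
License: MIT
Encoding: UTF-8
Imports:
    signal,
    pracma,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
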