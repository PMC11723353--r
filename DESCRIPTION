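Package: ppgthreat
Title: Threat Detection from Short Smartwatch Photoplethysmogram Windows
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects acute-threat (fear/arousal) states from 12-second,
    25 Hz wrist photoplethysmogram (PPG) windows such as those produced by
    commercial smartwatches. Raw windows are bandpass filtered (0.5-8 Hz),
    segmented into 27-sample beat-centered single pulses around validated
    systolic peaks, and screened with a 25,000-count amplitude threshold.
    A two-component Gaussian mixture model per class separates label-consistent
    ("normal") pulses from ambiguously labeled ("anomalous") ones, cleaning
    noisy training labels caused by non-responding participants and removing
    indiscernible test pulses. A compact one-dimensional convolutional network
    classifies single pulses, and a window-level verdict is issued when at
    least 33% of surviving pulse predictions are positive. Includes a seeded
    synthetic wrist-PPG generator for fully reproducible benchmarking,
    window-level evaluation metrics, and McNemar's paired classifier test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust
Config/testthat/edition: 3
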