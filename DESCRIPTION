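Package: finchsong
Title: Evoked-Response and Song-Learning Analysis for the Songbird
    Cerebello-Basal-Ganglia Circuit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse electrical-stimulation-evoked responses in
    song-related basal ganglia recordings and to quantify juvenile song
    learning in zebra finches. Implements peri-stimulus time histogram
    (PSTH) construction with baseline-band response detection (mean
    +/- 2.5 SD, two-consecutive-bin rule), response latency, strength and
    peak-rate measures, response-profile classification, and
    pharmacology-condition comparisons. Song analysis covers amplitude
    envelope computation, template-based motif detection, bout
    segmentation by the 500 ms silence rule, threshold-based syllable
    segmentation, autocorrelation fundamental-frequency estimation, and
    spectrogram cross-correlation similarity. Learning statistics group
    renditions into pre/post/crystallization periods and compute relative
    changes, coefficients of variation, learning trajectories, normalized
    imitation scores, lesion-size correlations and the associated
    nonparametric tests. A fully seeded synthetic-data generator produces
    spike-train sessions and multi-day song corpora with known ground
    truth for parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
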