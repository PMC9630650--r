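Package: graspemg
Title: Grasp Movement Decoding and Force Estimation from Surface EMG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An offline analysis pipeline for multichannel surface
    electromyography (sEMG) of natural grasping movements. Simulates
    synchronized EMG/force/trigger sessions with a channel-by-movement
    gain structure, filters and segments trials, extracts the five
    classical time-domain features (MAV, RMS, VAR, WAMP, WL) over
    sliding windows, classifies four grasps under three force levels
    with a cross-validated support vector machine including exhaustive
    electrode channel-subset scans, and estimates continuous grasp
    force (%MVC) with a feed-forward neural network evaluated by the
    coefficient of determination.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    nnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
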