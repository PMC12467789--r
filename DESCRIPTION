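Package: gaitfuse
Title: Pathological Gait Simulation, Phase Estimation and Angle-Phase Fusion Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for lower-limb gait analysis aimed at exoskeleton control
    research on pathological walking patterns. Provides a synthetic bilateral
    gait simulator for scissor, foot-drop and staggering gaits with exact
    ground-truth phase labels; a four-phase/four-stage discrete labeling
    scheme with bilateral coupling and trend-based event detection; gait-cycle
    length normalization by linear interpolation with ensemble mean and
    standard-deviation summaries; continuous gait-phase estimation by a pool
    of adaptive frequency oscillators with toe-off reset; construction of
    angle-phase fused sliding-window features; compact convolutional and
    recurrent networks for walking-stage classification and lower-limb angle
    prediction; and RMSE/Pearson evaluation with Kruskal-Wallis and Dunn
    model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
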