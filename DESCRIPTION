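Package: vrtrials
Title: Headless Trial-Based Virtual Reality Behavior Experiments and
    Kinematic Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A hardware-free framework for trial-based behavioral
    experiments in virtual reality. Provides factorial design generation
    and block-wise randomization, frame-locked recording of head, hand and
    gaze data with world-space gaze raycasting and fixated-object
    resolution, eye-tracker validation metrics (angular accuracy,
    precision and RMSE), seeded device simulators (head-mounted display,
    reaching hand controller with minimum-jerk kinematics, eye tracker
    with configurable bias and noise), a complete pro-/anti-reach example
    task driven entirely by simulated devices, and a kinematic analysis
    pipeline (velocity-criterion movement onset, latency, duration,
    endpoint error, outlier filtering and per-condition aggregation).
    Sessions serialize to a single JSON file and to per-trial and
    per-sample CSV tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    ggplot2,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
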