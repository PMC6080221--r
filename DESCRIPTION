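Package: myograsp
Title: Myoelectric Grasp-Force Level Classification and Closed-Loop Control Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for grasp-force control from multi-channel
    surface electromyography (sEMG): synthetic armband-style sEMG/force
    acquisition, time-domain feature extraction (MAV, RMS, SD, WL) over
    overlapping sliding windows, PCA dimension reduction, a stacked sparse
    autoencoder with a softmax head classifying eight grasp-force levels
    (0-40 N) plus per-level sEMG-to-force regressors, and a simulated
    fuzzy-controlled grasp loop with vibrotactile level feedback.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
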