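Package: coactr
Title: Coactivation and Kinematic Analysis of Rhythmic Elbow Flexion-Extension
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for quantitative assessment of upper-limb motor
    control from surface electromyography (sEMG) and inertial joint-angle
    recordings of rhythmic elbow flexion-extension. Conditions raw sEMG into
    normalized activity envelopes (Butterworth band-pass, block RMS,
    oversampling, baseline correction, peak normalization), segments movement
    cycles into acceleration/deceleration phases of flexion and extension from
    the angle trace and its angular velocity, and computes range-of-motion
    summaries, the agonist-antagonist coactivation coefficient, and
    muscle-synergy area shares. Includes a factorial (phase x speed) ANOVA
    layer with Tukey HSD post-hoc tests and Cohen's f effect sizes, and a
    synthetic-trial generator with analytic ground truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Imports:
    car,
    jsonlite,
    pracma,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
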