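Package: emgait
Title: Surface-EMG Gait Analysis for Stroke Rehabilitation Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to evaluate gait rehabilitation from multi-channel
    surface electromyography. Implements linear-envelope extraction,
    EMG-driven step segmentation from soleus deactivation with an adaptive
    moving-window threshold, time- and amplitude-normalized gait-cycle
    activation profiles, similarity indices against normative activation
    patterns (Gait Metric and Burst Duration Similarity Index),
    agonist-antagonist magnitude-squared coherence with band areas and
    multi-trial confidence limits, a composite clinical Capacity Score with
    minimum-detectable-change flags, and cohort-level comparisons. Includes
    a synthetic gait-EMG generator with known ground truth (step boundaries,
    activation windows, narrow-band common drive) for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
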