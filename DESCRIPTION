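Package: gazeproximity
Title: Proximity Index Analysis of Gaze Divergence During Dynamic-Stimulus Viewing
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies moment-to-moment divergence of an individual's gaze
    from a reference group's gaze distribution while viewing a dynamic
    stimulus. Builds frame-wise referent gaze densities by adaptive-bandwidth
    kernel density estimation, extracts 100-level isoline structure, and
    scores gaze coordinates with the Proximity Index (PI), a per-frame value
    in [0, 1] given by the highest containing isoline level. Includes I-VT
    velocity-threshold fixation filtering, screen-attendance quality control,
    focal/ambient fixation-mode taxonomy, bottom-up salience channel maps
    with ROC-AUC fixation-prediction evaluation, per-frame scene-feature
    timelines (Canny edge complexity, annotation rasterization, hard-cut
    detection), partial least squares correlation with permutation and
    bootstrap inference, sliding-window gaze-dispersion trajectories with
    permutation tests, and a synthetic-data generator with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, grDevices, graphics, jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
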