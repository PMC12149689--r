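Package: echoqc
Title: Interpretable Quality Control of Echocardiography Video
Version: 0.1.0
Authors@R:
    person("echoqc", "developers", email = "echoqc@example.org", role = c("aut", "cre"))
Description: Automated, interpretable quality control (QC) of apical
    four-chamber (A4C) echocardiography videos. Implements cardiac-cycle
    completeness analysis and end-diastole/end-systole keyframe detection
    via left-ventricular volume-curve regression, oriented-bounding-box
    anatomical structure analysis with circular smooth label angle coding,
    imaging-depth and cardiac-axis-angle quantification, gain
    classification, and a five-point rule-based scoring protocol. Includes
    a synthetic A4C phantom generator with exhaustive ground truth, a
    desk-scale trainable model stack (shared convolutional backbone,
    bidirectional LSTM phase regressor, oriented detection head, gain
    head) written in base R, evaluation metrics (frame error, rotated-box
    mAP, Cohen's kappa, ROC/AUC), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    png,
    yaml
Config/testthat/edition: 3
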