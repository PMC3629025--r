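Package: rtbold
Title: Reaction-Time-Controlled Analysis of Neural Congruency Effects
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for asking whether the neural congruency effect in
    distracter-interference tasks survives control for conditional
    differences in mean reaction time (RT). Implements trial-level
    event-related fMRI general linear models with polynomial RT
    modulators, canonical double-gamma haemodynamic convolution,
    discrete-cosine high-pass filtering and AR(1) prewhitening; three
    RT-control procedures (an RT-equating regression contrast, a
    tolerance-window maximum-cardinality RT-matching of congruent to
    incongruent trials, and a uniform-stride RT-subsampling control);
    sphere-ROI extraction and random-effects group statistics; and a
    calibrated synthetic multi-source-interference-task (MSIT) generator
    with known ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    readr,
    jsonlite,
    yaml,
    withr,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
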