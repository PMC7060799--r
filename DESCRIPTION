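Package: cinemetrics
Title: Quality-Controlled Ventricular Function Analysis from Cine Cardiac MRI Segmentations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Downstream analysis of segmented cine cardiac MRI exams:
    iterative short-axis/long-axis breath-hold alignment, biventricular
    volume curves with filling and ejection dynamics, feature-tracking
    myocardial strain, rule-based and learned post-analysis quality
    control, and cohort statistics (Bland-Altman agreement, error-detection
    summaries, stratified normative reference intervals). Ships a
    parametric biventricular phantom with analytic ground-truth volume
    curves, displacement fields and strain, so every stage of the pipeline
    can be exercised and validated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    e1071,
    stats,
    grDevices,
    graphics,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
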