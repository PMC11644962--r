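Package: thermoknee
Title: Knee Thermography and Balance-Board Analysis for Sit-to-Stand Exercise
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts knee-zone skin-temperature profiles from infrared
    thermal image sequences by two methods (operator-style rectangular
    region-of-interest extrema and tracked-keypoint sampling), processes
    four-load-cell balance-board recordings into per-leg weight shares,
    fore/rearfoot distribution and centre-of-pressure trajectories with
    sit-to-stand phase segmentation, and quantifies inter-method agreement
    with linear regression, residual RMSE, Bland-Altman limits and
    agreement labels. Includes a synthetic-cohort generator (thermal video,
    keypoint tracks, load-cell signals with known ground truth) so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    tiff,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
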