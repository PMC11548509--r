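Package: sitstand
Title: Distance-Based Representation of Sit-Stand Transitions from Sagittal Range Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to represent standing-up and sitting-down motions from a
    single side-mounted proximity (2D range-scan) sensor. A three-bar sagittal
    linkage models the lower limb and trunk; per-sweep point clouds are reduced
    to a valid body surface, knee and hip joints are located as curvature
    maxima with anthropometric validation, the sensor-to-body distance
    trajectory is tracked with a Gudermannian-type sigmoid, and a rule cascade
    labels each frame with one of six motion phases, a hold state, or a fall
    state. A ray-casting simulator of scripted sit-stand motions supplies
    labelled synthetic scan sessions for testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
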