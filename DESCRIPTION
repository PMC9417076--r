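Package: imuagree
Title: Concurrent Validity and Test-Retest Reliability of Wearable IMU Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the concurrent validity and test-retest
    reliability of free accelerations and orientations recorded by wearable
    inertial measurement units (IMUs) during functional activities (squats,
    jumps, walking, stair ambulation). Implements the full processing chain:
    quaternion to intrinsic z-x-y Euler conversion, zero-phase low-pass
    Butterworth filtering, movement-cycle segmentation from thigh-orientation
    extrema, time-normalization of cycles to a 0-100 percent grid, and
    per-cycle range outcomes. Agreement between a test and a criterion device
    is quantified with the Linear Fit Method (slope, intercept, r-squared) and
    Bland-Altman statistics; between-session reliability with the two-way
    random-effects consistency intraclass correlation coefficient ICC(C,1),
    its F-based confidence interval, and the standard error of measurement.
    Includes a synthetic dual-sensor cohort generator with known distortion
    and variance-component parameters so every estimator can be verified by
    parameter recovery, and the Walter-Eliasziw-Donner sample-size procedure
    for reliability studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
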