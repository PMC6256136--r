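Package: skipower
Title: Propulsive Power Estimation for Roller-Skiing from Wearable GNSS and IMU Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the propulsive power generated by a (roller-)skier from
    body-worn sensors using the power-balance principle. Processes 10 Hz GNSS
    position streams against a high-accuracy reference trajectory of the course
    (smoothing splines, zero-phase Butterworth filtering, arc-length map
    matching, five-point finite differences), derives posture from torso and
    thigh inertial measurement units (pitch angles, tuck detection from
    gyroscope energy), models aerodynamic drag with a posture-dependent frontal
    area and a Reynolds-dependent drag coefficient, models rolling resistance
    including centripetal loading, and inverts the power balance to per-second
    propulsive power and force. Includes Monte Carlo propagation of wind,
    drag-area, drag-coefficient and rolling-resistance uncertainty into the
    power estimate, a sensitivity (discriminability) analysis, and a
    forward-dynamics simulator of races with synthetic sensor streams so the
    whole pipeline can be verified without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    signal,
    MASS,
    jsonlite,
    yaml,
    xml2
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    optparse
Config/testthat/edition: 3
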