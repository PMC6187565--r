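Package: imugait
Title: Wearable Inertial Sensor Gait Analysis via Multi-Sensor Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end gait analysis from body-worn inertial measurement
    units (IMU/MARG): constrained ellipsoid-fit calibration of accelerometer
    non-orthogonality and magnetometer hard/soft-iron distortion, quaternion
    attitude estimation by a proportional-integral complementary filter,
    zero-velocity-update (ZVU) aided strapdown position integration,
    stance/swing detection, spatio-temporal gait parameters (stride length,
    speed, cadence, clearance, knee range of motion) and bilateral-symmetry
    statistics.  Ships a parametric lower-limb gait simulator that produces
    ground-truth kinematics and realistic raw sensor streams for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
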