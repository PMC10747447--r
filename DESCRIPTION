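Package: mvkin
Title: Multi-View Markerless Kinematics and Concurrent-Validity Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for validating markerless multi-camera motion capture
    against a reference motion-capture system. Simulates articulated trunk
    and lower-limb motion (standing side dip, Y-balance posterolateral
    reach) viewed by a ring of calibrated pinhole cameras, triangulates 2D
    body keypoints to 3D by the direct linear transform, computes
    anatomical joint angles (hip flexion, knee flexion, signed trunk
    side-bending) from a torso coordinate frame, time-normalises paired
    angle traces to a common 100-frame grid, and quantifies agreement with
    intraclass correlation coefficients (ICC(2,1), ICC(3,1), ICC(3,k)) with
    exact F-based confidence intervals, the method-error coefficient of
    variation, the standard error of measurement, and the minimal
    detectable change.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
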