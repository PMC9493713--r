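Package: strikekin
Title: Marker-Based Suction-Feeding Strike Kinematics and Buccal Volume Dynamics
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for turning frame-indexed 3D marker trajectories from
    biplanar videoradiography (XROMM-style recordings) into rigid-body pose
    series, joint-coordinate-system (JCS) Euler kinematics, muscle strain,
    prey kinematics, dynamic alpha-shape endocasts of the oral cavity, and
    each bone's relative contribution to volume change (RCVC) during suction
    feeding strikes. Includes a forward-kinematics generator of synthetic
    articulated-skull strike datasets with known ground truth for validation,
    zero-phase Butterworth filtering, marker- and JCS-level precision
    analysis, strike event detection, trial alignment and averaging, and an
    interspecies body-length regression utility.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
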