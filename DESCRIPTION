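Package: kinectMJT
Title: Automated Timing of the Modified Jebsen Test of Hand Function from
    RGB-D Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects scene geometry, tracks the hand and times the three
    subtests of the Modified Jebsen Test of Hand Function (card turning,
    simulated feeding, stacking checkers) from top-down RGB-D frame
    sequences such as those produced by a Microsoft Kinect mounted above a
    table. Includes depth-image segmentation of the table, board, ridge and
    can, 4-connected hand tracking with distal-centroid computation, task
    event detectors (green card markers, frame-differencing bean drops,
    depth-interval checker stacking), movement-onset start detection, the
    repeated-measures Bland-Altman agreement statistics used to compare
    timing methods, and a synthetic RGB-D scene simulator with exact
    ground-truth times for validating every detector without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    car,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
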