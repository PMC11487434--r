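Package: vertrot
Title: Automated Vertebral Rotation Angle Measurement from 3D Point Clouds
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for measuring the axial rotation angle of single vertebrae
    from 3D surface point clouds, a key severity parameter in idiopathic
    scoliosis. Provides entropy-augmented farthest-point sampling for uniform
    fixed-size downsampling of unevenly dense vertebral clouds, a pure-R
    relation-attention point-cloud segmentation network for predicting
    endplate and pedicle regions, geometric construction of the vertebral
    local coordinate frame and transverse-plane rotation angle from the
    predicted landmarks, and the agreement statistics (Bland-Altman limits of
    agreement, two-way absolute-agreement intraclass correlation) used to
    validate automated against manual measurements. A synthetic vertebra
    phantom generator with exact ground truth supports end-to-end testing
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
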