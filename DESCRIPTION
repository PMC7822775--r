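Package: xrnav
Title: Projection Geometry, Registration and Tracking for X-Ray
    Fluoroscopy Guidance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computational core of an X-ray navigation guidance system for
    transcatheter interventions: C-arm pinhole projection geometry with
    continuously updatable projection matrices, biplane epipolar
    triangulation of 3D working points, paired-point rigid 3D-3D
    registration with RMSE reporting, normalized cross-correlation template
    tracking with 2D and 3D motion compensation, template-matching
    character recognition of live-video geometry panels, closed-form bounds
    on overlay misalignment caused by display rounding of geometry values,
    a synthetic sphere-phantom and frame simulator providing ground truth
    for every component, and readers/writers for DICOM geometry metadata
    and legacy VTK polygonal meshes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
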