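Package: sijdowel
Title: Bone Quality Along Virtual Implant Trajectories in Sacroiliac CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies bone quality along virtual cylindrical implant
    trajectories ("dowels") crossing the sacroiliac joint in CT volumes.
    Builds 12 mm cylindrical regions of interest from fiducial pairs,
    classifies voxels into cortical and cancellous bone by calibrated
    Hounsfield-unit thresholds, computes per-trajectory density and
    bone-fraction metrics, maps the joint gap as the closest distance
    between opposing bone surfaces inside each dowel, and summarises a
    cohort with repeated-measures and two-way analyses of variance with
    Bonferroni-corrected post hoc comparisons. Includes a digital phantom
    generator (two cortical-shelled bodies separated by a configurable
    joint gap, plus density-calibration inserts) so the whole pipeline is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
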