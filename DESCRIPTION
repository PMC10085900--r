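Package: clavloc
Title: Slice-Wise Object Detection for Localizing the Sternoclavicular
    Joint Region in CT Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Automated localization of the sternoclavicular joint region
    (a proxy for the medial clavicular epiphyseal cartilages used in
    forensic age assessment) in chest CT volumes.  A compact one-stage
    anchor-based object detector with focal loss is trained on axial
    slices; per-slice detections are aggregated to a unique 3D location
    estimate (x, y, slice) by selecting the highest classification
    score.  Includes Hounsfield-unit preprocessing, bounding-box
    annotation handling, VOC-style interpolated average-precision
    evaluation with per-scan localization categories, and a synthetic
    chest-CT phantom generator so the full pipeline is testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    RNifti,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
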