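Package: elbowqc
Title: Automated Positioning Quality Control of Elbow-Joint Radiographs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Automated positioning quality control (QC) of elbow-joint
    radiographs from keypoint and bounding-box annotations. Implements five
    geometric QC criteria for anteroposterior (AP) and lateral (LAT)
    projections (elbow centering, olecranon-fossa centering via the S17/S27
    distances, joint-space ordering, trochlea centering, and the flexion
    angle), detection-evaluation metrics (IoU, object keypoint similarity,
    precision, recall, mAP50, mAP50-95), intraclass-correlation agreement
    analysis between model and human raters, annotation interchange in
    Labelme-style JSON and YOLO-pose text dialects, DICOM windowing and
    letterbox preprocessing to the 640x640 model frame, and a synthetic
    annotation generator with controllable positioning faults so the whole
    pipeline is testable without clinical images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    EBImage,
    png,
    jpeg
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
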