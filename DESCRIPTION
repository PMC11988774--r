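Package: proxcaries
Title: Proximal Caries Diagnosis and Detector Evaluation for Bitewing
    Radiographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: A detector-agnostic pipeline for diagnosing proximal carious
    lesions on bitewing radiographs. Converts between COCO and YOLO
    annotation dialects, applies CLAHE contrast enhancement and
    coordinate-aware resizing, assigns each detected lesion to an affected
    FDI-numbered tooth and surface (mesial/distal) via a three-scenario
    bounding-box overlap algorithm, and scores detections with
    IoU-threshold matching (precision, recall, F1, average precision,
    macro mAP). Includes a synthetic bitewing scene generator with a
    perturbation-based mock detector so the full pipeline is testable
    without clinical images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    optparse,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
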