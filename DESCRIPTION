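Package: podmetrics
Title: Coin-Calibrated Morphometry of Rapeseed Pods from Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Measures length, width and area of rapeseed (Brassica napus)
    pods from photographs of pods laid on a dark background next to a
    reference coin of known diameter. A threshold-based segmentation stage
    extracts object contours; the coin provides pixel-to-millimetre
    conversion ratios; per-pod traits are derived from contour perimeter
    and area. Also included: a seeded synthetic scene generator with exact
    ground truth, Labelme-to-COCO annotation conversion,
    annotation-consistent image augmentation, and COCO-style instance
    segmentation evaluation (precision/recall, AP at IoU thresholds,
    size-stratified AP).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    withr,
    stats,
    grDevices,
    utils,
    tools
Suggests:
    optparse,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
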