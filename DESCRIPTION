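Package: stripreader
Title: Automated Colorimetric Reading of Urine Test Strips from Photographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reads 10-parameter urine test strips (dipsticks) from smartphone
    photographs. Locates the printed color reference card by binary-descriptor
    feature matching and rectifies it with a robustly estimated homography,
    localizes the strip's test fields by a multi-setting edge-detection and
    k-means clustering procedure with automatic grid completion, extracts each
    field's dominant HSV color by histogram peak, scores it against the card's
    graded reference levels with three similarity measures (circular hue
    difference, a weighted HSV matching factor, and Euclidean distance in HSV
    cylinder coordinates), and classifies each analyte as negative or positive
    using standard clinical rules. A seeded synthetic scene generator renders
    card-plus-strip scenes with full ground truth so the entire pipeline is
    testable without photographs, and an evaluation harness reports per-analyte
    confusion matrices and F1 scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
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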