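Package: exudatekit
Title: Exudate Detection and Severity Assessment in Retinal Fundus Images
Version: 0.1.0
Authors@R: person("exudatekit", "maintainers", email = "maintainers@exudatekit.org",
    role = c("aut", "cre"))
Description: Detection of hard and soft exudates, an early pathological sign of
    diabetic retinopathy, in colour fundus photographs. Provides denoising
    (weighted linear smoothing followed by masked median filtering), green/red
    hue-ratio equalization to a common colour operating point, colour-range
    exudate segmentation with elliptical region annotation and a maximal-region
    severity flag, histogram and texture enhancement (48-bin histograms, GLCM,
    adaptive histogram equalization and per-channel CLAHE), a small
    convolutional patch classifier built around a geometric-mean parametric
    ReLU activation, binned survival-fraction ROC evaluation with
    rectangle-rule AUC, and a seeded synthetic fundus generator with ground
    truth masks so the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    png,
    jpeg
Config/testthat/edition: 3
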