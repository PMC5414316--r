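Package: gblupcv
Title: Efficient Leave-One-Out Cross-Validation for Genomic BLUP
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits ridge-type genomic BLUP under the marker-effect model
    (MEM) and the equivalent breeding-value model (BVM), and computes
    leave-one-out cross-validation (LOOCV) residuals, PRESS, prediction
    accuracy, prediction error variance and reliability without refitting:
    via the hat-matrix leverage identity (MEM and BVM strategy I) and via a
    single inverse of a phenotype-augmented covariance matrix (BVM strategy
    II). A naive refitting oracle, a random-mating population simulator and
    a command-line interface are included.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
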