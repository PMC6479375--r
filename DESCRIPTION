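Package: delda
Title: Differential Entropy and Linear Discriminant Feature Extraction for Emotion EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature extraction for multi-channel emotion EEG: decomposes trials
    into the canonical delta/theta/alpha/beta/gamma bands with zero-phase
    Butterworth filters, computes per-band differential entropy of the
    band-limited (approximately Gaussian) signals, and fuses the resulting
    features with a multi-class Fisher linear discriminant projection solved as
    a generalized eigenproblem on the within- and between-class scatter
    matrices. Includes a repeated stratified-split benchmark harness over five
    reference classifiers (k-NN, logistic regression, MLP, random forest, SVM)
    with accuracy, macro precision/recall/F1 and Cohen's kappa, a synthetic
    band-limited Gaussian EEG generator with class-conditional band power for
    fully reproducible end-to-end testing, and EDF input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    class,
    e1071,
    graphics,
    grDevices,
    jsonlite,
    nnet,
    ranger,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    signal,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
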