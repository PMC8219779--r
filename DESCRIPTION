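Package: kmcloc
Title: Grid-Box Lesion Localization with Small Neural Networks Trained by
    the Kim-Monte Carlo Algorithm
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Coarse localization of lesions (such as pneumothorax) in
    grayscale radiograph-like images by predicting one score per cell of a
    fixed 7x7 grid. Small fully-connected networks and a tree-structured
    per-map convolution network are trained without gradients by the
    Kim-Monte Carlo algorithm: random subsets of weights and biases are
    perturbed by small uniform amounts and changes are kept only when the
    mean training error decreases. Includes a seeded synthetic image
    generator with exact lesion masks, grid/resolution preprocessing,
    pooled per-box ROC analysis with Youden-index cutoff selection, and
    colored box overlay rendering.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
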