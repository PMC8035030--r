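Package: rankvision
Title: Multilevel Taxonomic Image Classification with Multi-Head Softmax Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A backbone-agnostic framework for classifying organism images at
    every rank of a taxonomic hierarchy at once. A shared convolutional feature
    extractor feeds one softmax head per rank (Kingdom through Species), trained
    with categorical cross-entropy, Adam, and patience-based early stopping.
    The package implements three augmentation regimes (standard operators,
    central crop, multiscale crop) with class balancing to the most represented
    category, three ensemble schemes (accuracy-weighted boosting, stacked
    meta-classifier, and a phylum-routed cascade of specialists), a per-rank
    evaluation protocol (top-k accuracy, weighted F1, macro AUC, normal fit to
    the per-class F1 distribution), readers for iNaturalist-competition
    annotation JSON and flat CSV manifests, and a fully synthetic hierarchical
    image generator so the whole stack is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    jsonlite,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    EBImage
Config/testthat/edition: 3
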