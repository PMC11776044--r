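Package: phenocon
Title: Semisupervised Contrastive Representation Learning for High-Content
    Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Learns latent representations of compound-induced morphological
    perturbations from multi-channel high-content (Cell Painting style)
    microscopy images by semisupervised contrastive learning: replicate images
    of the same treatment act as self-supervised positives, and shared
    bioactivity annotations (e.g. MeSH pharmacological classes) define
    supervised positives on the annotated subset. The learned embeddings feed
    downstream random-forest and multilayer-perceptron classifiers for
    single-label and multilabel bioactivity prediction under grouped
    cross-validation, with per-class precision/recall/F1 deconvolution,
    exact-match multilabel accuracy and macro-averaged precision-recall AUC.
    Unannotated compounds are ranked by their batchwise self-supervised
    contrastive loss and annotated with the most frequently predicted classes
    across replicates. A synthetic Cell-Painting-like image generator with
    known latent class structure, replicate/batch effects, vehicle controls
    and partial annotation makes the whole workflow testable without any
    external image download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tiff,
    EBImage,
    ranger,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
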