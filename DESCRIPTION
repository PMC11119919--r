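Package: protopart
Title: Prototype-Part Attention Networks for Interpretable Image Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Case-based interpretable image classification with prototype-part
    attention. A convolutional feature extractor is followed by a multi-part
    attention layer that scores the L2 similarity between learned class-specific
    feature patterns (prototypes) and every latent patch of an input image, and a
    similarity-based classifier that forms class logits from the top-ranked
    weighted similarity scores. Training alternates stochastic gradient descent
    on a cross-entropy + cluster + separation objective with prototype projection
    onto real latent patches of a push dataset and a convex re-fit of the
    non-negative class-connection weights. The package provides global
    explanations (the learned feature patterns with their source patches) and
    local explanations (ranked top-10 reasoning tables with bounding boxes and
    weighted scores), reliability screening of individual predictions, prototype
    quality control, and a seeded two-class lesion-phantom generator with
    ground-truth masks so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    glmnet,
    grDevices,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    RNifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
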