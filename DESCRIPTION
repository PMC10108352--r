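Package: latentheal
Title: Unsupervised Anomaly Segmentation by Vector-Quantized Latent Healing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Unsupervised anomaly detection and segmentation for brain-like
    2D images and 3D volumes. A vector-quantized autoencoder compresses an
    image to a discrete latent grid; an ensemble of autoregressive sequence
    models, one per space-filling ordering of the grid (raster, S-curve,
    Hilbert, random), scores each latent token's likelihood; low-likelihood
    tokens are "healed" by conditional resampling and the decoded healed
    image yields mask-filtered residual maps for pixel-wise segmentation.
    Sequence log-likelihoods provide image-wise out-of-distribution scores,
    optionally combined with predicted lesion volume through a one-class
    support vector machine. Includes a synthetic head-phantom and sprite
    generator so the full pipeline is trainable and testable without any
    external dataset, plus best-achievable-DICE, AUPRC, AUROC and FPR-at-TPR
    evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    generics,
    ggplot2,
    jsonlite,
    png,
    RNifti,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
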