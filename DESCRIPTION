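Package: fundistill
Title: Token-Reconstruction Pretraining and Evaluation for Retinal Fundus Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Self-supervised pretraining of a small vision transformer on colour
    fundus photographs by token reconstruction: a trainable student receives
    corrupted images (patch embeddings replaced by a learnable corruption token,
    plus pixel-wise Gaussian noise) and is trained to reproduce the output tokens
    that a frozen copy of the same network computes from the clean images. The
    package provides the full surrounding workflow: a deterministic synthetic
    fundus generator for testing, fundus-area detection and square crop/pad
    preprocessing, the training-time augmentation recipe, embedding extraction
    and checkpoint stripping, linear probing and 2-D projection evaluation
    (PCA/UMAP), paired-bootstrap Wilcoxon model comparison, and GPU-day / cost
    accounting arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    glmnet,
    pROC,
    class,
    png,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
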