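Package: lesiondet
Title: Masked-Patch Pretraining and Windowed Attention for Small-Lesion Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale implementation of a three-stage pipeline for detecting
    small, low-contrast targets in noisy grayscale images: masked-patch
    self-supervised reconstruction pretraining (a masked autoencoder over a
    patch-token sequence), a hierarchical backbone of window-local and
    shifted-window multi-head self-attention with patch merging, and a
    single-stage anchor-based detection head over an FPN+PAN feature pyramid,
    trained with a -ln(IoU) box loss and per-class binary cross-entropy.
    Includes a reproducible synthetic small-lesion image generator (PNG images
    with YOLO text or COCO JSON annotations), COCO-style 101-point average
    precision with size-banded variants, a composite mAP, and a small
    reverse-mode automatic-differentiation tape on which all training runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    yaml,
    stats,
    utils,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
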