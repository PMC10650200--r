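Package: dhunet
Title: Dual-Phase Hyperactive UNet for Chronic Wound Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Implements DHuNeT, a dual-phase segmentation network for chronic
    wound (ulcer) photographs: two sequentially stacked UNet encoder-decoders
    in which the second UNet receives the first UNet's predicted mask alongside
    the image and averages the first UNet's encoder, decoder, and bottleneck
    feature maps into its own at every level ("hyperactive" feature transfer).
    Includes the contour-based region-of-interest preprocessing pipeline
    (median/Gaussian blur, thresholding, largest-contour crop, resize),
    binary cross-entropy and soft-Dice training objectives with pixel-wise
    precision/recall/F1/Dice evaluation, an Adam-based training loop with
    deep supervision of both mask heads, and a deterministic synthetic
    wound-image generator for end-to-end testing without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
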