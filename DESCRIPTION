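Package: seunet
Title: Nested U-Net Segmentation with Squeeze-and-Excitation Attention for Liver Lesion CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds, trains and evaluates nested residual U-block ("U2") encoder-decoder
    segmentation networks for liver occupying lesion segmentation in abdominal CT,
    including the squeeze-and-excitation (SE) channel-attention variant in which the
    residual branch of each non-dilated residual U-block is recalibrated by an SE unit.
    Provides the hybrid cross-entropy + Dice training loss, pixel-confusion evaluation
    metrics (IoU, accuracy, Cohen's kappa, Dice), a cosine-annealed momentum training
    loop with checkpointing, CT-volume preprocessing from NIfTI to 2D PNG slice pairs
    with PUFH-style and LiTS-style label conventions, a structural complexity audit of
    the assembled networks, and a seeded synthetic CT phantom generator so the whole
    pipeline is exercisable at desk scale on CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    png,
    jsonlite,
    yaml,
    stats,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    e1071
Config/testthat/edition: 3
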