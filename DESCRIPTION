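Package: halfunet
Title: Half-UNet Segmentation Networks with Analytic Complexity Accounting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Builders for the Half-UNet family of encoder-decoder medical
    image segmentation networks and their comparison baselines (U-Net,
    UNet3+-style full-scale aggregation, ablation encoders), together with
    an analytic parameter and FLOP accounting engine, Dice-based evaluation
    metrics, a synthetic segmentation dataset generator emulating
    mammography mass, lung-nodule and left-ventricle regimes, and a pure
    CPU training runtime (im2col convolutions, Ghost modules, Adam, Dice
    loss) so that every network can be built, counted, trained and
    evaluated without external datasets or a deep-learning framework.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
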