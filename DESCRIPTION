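Package: lumenpulse
Title: Quantification of Stimulus-Evoked Penetrating Arteriole Dilation from
    Two-Photon Cross-Section Movies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for measuring neurovascular coupling (NVC) responses of
    brain penetrating arterioles imaged in cross-section by two-photon
    microscopy. Per-frame vessel diameter is measured as the minimum chord
    through the centroid of the binarized lumen, normalized to the pre-stimulus
    basal diameter, averaged across stimulation trials, and summarized by four
    response parameters (amplitude, time to peak, time to half-maximal
    dilation, and area under the curve). Includes a seeded synthetic-movie
    generator with known ground truth for benchmarking, intrinsic optical
    signal activity mapping, nested (arteriole-within-mouse) group statistics,
    and longitudinal percent-change comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    rlang,
    stats,
    utils,
    generics,
    ggplot2,
    tiff,
    yaml,
    EBImage,
    lme4,
    lmerTest,
    emmeans
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    purrr,
    optparse,
    jsonlite
Config/testthat/edition: 3
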