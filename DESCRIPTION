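Package: tailbudkit
Title: Quantitative Image Analysis of the Zebrafish Tailbud
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for quantifying zebrafish tailbud ablation experiments from
    multi-channel 3D microscopy: nuclear segmentation by 2D labelling and
    IoU-based 3D label stitching, per-nucleus HCR expression quantification
    and neuromesodermal (sox2/tbxta) state classification, rigid point-cloud
    registration and local neighbourhood expression averaging across embryos,
    mean-squared-displacement analysis of cell tracks, and tail-tissue
    morphometrics with somite-number normalisation. Includes a synthetic
    phantom generator with attached ground truth so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
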