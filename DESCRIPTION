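Package: mitonet3d
Title: Quantification of 3D Mitochondrial Networks from Live-Cell Confocal Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments mitochondrial objects from dye-stained confocal z-stacks
    (3D median and white top-hat filtering, constant-value thresholding,
    26-connected component labelling), computes per-object and per-cell
    morphometrics (object volumes, intensities, nucleus/cell/cytoplasm volumes,
    size-class profiles), and quantifies photostability under repetitive
    imaging via Gaussian maximum-likelihood regression of relative ROI
    intensity with joint location and dispersion models compared by AIC.
    Includes a synthetic three-channel stack simulator with exact ground
    truth for validating the full pipeline.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    tiff,
    jsonlite,
    readr,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
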