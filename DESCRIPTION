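Package: nodulecad
Title: Lung Nodule Computer-Aided Detection on Chest CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A four-stage computer-aided detection (CAD) pipeline for pulmonary
    nodules on chest CT: lung extraction by minimum-error (Kittler-Illingworth)
    histogram thresholding with slice-wise hole filling, per-slice structure
    filtering followed by 3D candidate formation under 26-connectivity with
    blob-shape discrimination, an eight-descriptor shape/histogram feature set
    with pairwise-correlation feature selection, and an RBF-kernel
    epsilon-support-vector classifier with joint min-max normalization and a
    balanced training matrix. Includes an annotated synthetic thoracic phantom
    generator (two-material body/lung histogram, vessel trees with
    bifurcations, isolated/juxtapleural/vascular nodules) so the full pipeline
    is exercisable and testable without clinical data, plus leave-two-out
    cross-validation, sensitivity/specificity/accuracy and false-positives-per-
    scan evaluation, and ROC analysis over the epsilon parameter.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    EBImage,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    RNifti,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
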