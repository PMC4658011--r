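Package: radbpe
Title: Radiomics of Tumor and Background Parenchymal Enhancement on DCE-MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A reproducible pipeline for discriminating triple-negative breast
    cancer from other molecular subtypes on dynamic contrast-enhanced MRI.
    Covers 3-D segmentation of breast, tumor, fibroglandular parenchyma and
    adipose compartments; pharmacokinetic enhancement maps (rate-in, percent
    enhancement, signal enhancement ratio); first-order and 26-direction 3-D
    gray-level co-occurrence texture features; fold-encapsulated chi-squared
    ranking, sequential forward floating selection and linear support vector
    machine classification under repeated stratified cross-validation; and
    unsupervised k-means partitioning of background parenchymal enhancement
    textures. Includes a synthetic phantom and feature-table generator so the
    whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    RNifti,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr,
    pheatmap
Config/testthat/edition: 3
RoxygenNote: 7.3.3
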