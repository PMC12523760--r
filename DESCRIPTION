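Package: fibroscope
Title: Quantitative Fibrosis Phenotyping for Trichrome-Stained Cardiac Histology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Quantitative image analysis of Masson's trichrome stained
    myocardial sections: colour deconvolution and collagen segmentation,
    single-fiber skeleton morphometry with fine/assembled classification,
    gray-level co-occurrence (GLCM) entropy mapping, endocardial/myocardial
    compartment analysis from polygon annotations, extraction of a catalog of
    quantitative fibrosis traits (qFTs), and their integration into four
    equi-weighted composite fibrosis scores compared between biopsy regions
    with exact Mann-Whitney U tests. Includes a synthetic trichrome study
    generator with per-fiber ground truth for validation and benchmarking.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    e1071,
    jsonlite,
    pracma,
    png,
    tiff,
    withr,
    grDevices,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
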