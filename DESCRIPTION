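Package: ExplainDR
Title: Explainable Cancer Drug Response Prediction from Multi-Omics and
    Drug Structure
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for explainable prediction of
    cancer cell line drug sensitivity. Gene sequences are decomposed into
    sliding windows, structural events (insertion, deletion, inversion,
    mirror, duplication) are detected and organised into neighbor-joining
    segment trees whose patristic-distance maps, together with rasterised
    drug depictions, form fused image tensors. Deep convolutional features
    with decimal-scaling normalisation and handcrafted texture descriptors
    (GLCM, LBP, local tetra patterns) are concatenated with annotation
    attributes, reduced by a Smoluchowski-guided kookaburra wrapper
    optimizer, and classified with an Aranda-activated graph attention
    network. Kernel SHAP attribution, hypergeometric pathway
    over-representation, and four-parameter logistic dose-response
    agreement analysis provide orthogonal biological validation. A
    synthetic-cohort generator with planted, recoverable signal makes every
    stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    ape,
    igraph,
    minpack.lm,
    glmnet,
    ChemmineR,
    ChemmineOB,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
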