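Package: radiostage
Title: Radiotranscriptomic Staging of Prostate Cancer from Ultrasound
    Radiomics and Stage-Specific Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for radiotranscriptomic staging analysis of
    prostate cancer: grayscale ultrasound texture and wavelet feature
    extraction over a region of interest (global first-order, GLCM, GLRLM,
    GLSZM and NGTDM families across two levels of Haar decomposition),
    contrast-enhanced ultrasound refill-curve fitting to microvascular
    perfusion parameters, correlation-based stepwise feature selection,
    stage-specific differential expression with Venn set logic and a
    six-biomarker filter, radiomic-expression correlation maps with
    canonical correspondence analysis, multi-model staging evaluation with
    a rank-based AUC, and miRNA-target regulatory network hub ranking.
    Because the motivating cohort is private, a seeded synthetic-study
    generator reproduces the statistical structure every stage assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    minpack.lm,
    png,
    yaml,
    jsonlite,
    randomForest,
    e1071
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
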