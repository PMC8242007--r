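Package: amniotime
Title: Amniotic Fluid Cell-Free Transcriptome Analysis and Time-to-Delivery
    Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for amniotic fluid cell-free RNA profiles from
    women with an episode of spontaneous preterm labor: linear-model batch
    correction and principal component analysis, gene-wise linear models with
    empirical-Bayes variance moderation and joint fold-change/FDR calling,
    tissue and placental cell-type signature Z-scoring with group comparison,
    hypergeometric gene-set enrichment, sparse HSIC (kernel dependence) feature
    selection with leave-one-out cross-validated random-forest regression of
    time-to-delivery, selection stability and consensus analysis, and clinical
    table statistics (Welch's t, Fisher's exact). Includes a synthetic cohort
    generator emulating the study design so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    pROC
Config/testthat/edition: 3
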