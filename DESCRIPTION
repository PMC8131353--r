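Package: retinaprog
Title: Disease-Progression Transcriptomics of the Diabetic Retina
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable, tested implementation of a bulk mRNA/miRNA
    transcriptome analysis pipeline for staged retinal disease such as
    diabetic retinopathy. Covers log2-CPM normalization with expression
    filtering, technical-replicate detection, surrogate-variable
    confounder residualization, moderated group-vs-healthy differential
    expression, a stage-position-learning sparse partial least squares
    model optimized by scatter search under repeated cross-validation to
    identify disease-progression transcripts, hypergeometric and
    fold-change-distribution gene-set enrichment, miRNA-target
    anti-correlation testing with evidence integration, and
    single-cell-informed marker analysis plus weighted non-negative
    least squares cell-type deconvolution. Ships a synthetic study
    generator that plants every structure the pipeline is designed to
    detect, so the whole analysis can be exercised and validated
    end-to-end without access to protected patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    limma,
    Matrix,
    mclust,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
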