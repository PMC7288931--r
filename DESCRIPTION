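Package: omicweave
Title: Integrative Genomic and Epigenetic Subtyping of Tumor Multi-Omics Data
Version: 0.1.0
Authors@R: person("omicweave", "developers", email = "omicweave@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable pipeline for integrative analysis of tumor
    copy-number, DNA-methylation and expression data. Builds gene-level
    matrices from segment tables and 450k-style probe matrices, screens for
    copy-number-driven and methylation-driven genes by Spearman correlation
    with a Fisher-type z transform, derives molecular subtypes by consensus
    non-negative matrix factorization and by a lasso-penalized joint
    latent-variable model, quantifies per-sample aberration burdens, and
    tests subtype associations with clinical features, mutation spectra and
    survival. Ships a coupled multi-omics simulator with planted subtype
    structure so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
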