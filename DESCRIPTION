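Package: tbvnet
Title: Blood Co-Expression Networks and Brain Size Variation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Weighted gene co-expression analysis linking a blood
    transcriptome to total brain volume (TBV): soft-threshold network
    construction and topological-overlap module detection, module
    eigengene and gene-set association with an age-adjusted trait using
    permutation and bootstrap inference, gene-level significance and
    intramodular connectivity reorganization statistics, small- versus
    big-brain relevance classification, module preservation (Zsummary,
    medianRank) between datasets, and hypergeometric gene-set
    enrichment. Includes a synthetic-data generator that plants known
    module structure and trait coupling so every stage is testable with
    ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    splines,
    stats,
    utils,
    withr
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
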