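Package: cadfam
Title: Signature-Site Classification, Phylogeny and Co-Expression Analysis
    for CAD Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable, tested pipeline for cinnamyl alcohol dehydrogenase
    (CAD) gene-family studies: classifies proteins by joint presence of the
    catalytic Zn-binding, structural Zn-binding and NADP(H)-binding signature
    sites with configurable mismatch tolerance; builds neighbor-joining trees
    from aligned peptides with column-resampling bootstrap support; scans 2 kb
    promoter regions for named cis-acting elements on both strands; filters
    FPKM expression matrices, prepares log2 heatmap matrices and calls
    stress-responsive genes by fold change; and thresholds pairwise Pearson
    correlations into positive/negative co-expression networks. Ships a
    synthetic-data generator with a ground-truth ledger so every stage is
    testable without external genome or transcriptome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    igraph,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
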