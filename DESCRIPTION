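Package: methcart
Title: Clone-Level CpG Methylation Calling and Decision-Tree
    Classification for Bisulfite Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tidy pipeline for targeted bisulfite amplicon sequencing of
    single hematopoietic colony-forming-cell (CFC) clones: barcode
    demultiplexing of multiplexed reads, alignment to a theoretical
    bisulfite-converted reference, per-read CpG methylation scoring with
    bisulfite conversion-efficiency estimation, hyperbolic PCR
    amplification-bias correction calibrated from methylated:unmethylated
    control mixtures, per-site statistical comparison of expressing and
    non-expressing clones, and a from-scratch classification tree over
    per-site methylation frequencies with deviance-based splitting and
    AIC cost-complexity pruning. Includes a synthetic read generator so
    the whole pipeline is testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    S4Vectors,
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
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
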