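Package: pooldelta
Title: Pooled-DNA QTL-Seq Analysis of Case/Control Exome Pools
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for detecting trait-associated loci from whole-exome
    sequencing of pooled genomic DNA in a case/control design. Computes per-site
    SNP indices (variant-read fractions) and their case-minus-control differences
    (delta SNP index) through a staged filter cascade, smooths them with sliding-window
    trendlines on genomic or spacer-concatenated coordinates, attaches Monte-Carlo
    confidence bands under the no-QTL null, and compares two disease contrasts
    region-by-region with exact/approximate Wilcoxon signed-rank tests under
    Bonferroni and Storey false-discovery-rate control. Includes a synthetic
    pooled-exome data generator with plantable allele-frequency shifts for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    rlang,
    vcfR,
    IRanges,
    S4Vectors,
    ggplot2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
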