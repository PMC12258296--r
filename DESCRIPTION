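Package: xconcord
Title: Cross-Platform Transcriptome Concordance Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing agreement between gene-expression counts
    measured on the same samples by two platforms, typically whole-transcriptome
    3'-tag RNA sequencing and a fixed hybridization counting panel of ~800
    genes. Implements the common count normalizations (CPM, TMM, RLE, and the
    two-step positive-control/housekeeping panel normalization), sample-wise
    and gene-wise correlation profiling with expression-strata summaries, a
    self-contained two-group negative-binomial Wald test with normal-prior
    log2 fold-change shrinkage and Benjamini-Hochberg/Benjamini-Yekutieli
    adjustment, and a concordance layer reporting annotation overlap, fold
    change correlation, per-gene direction classes, Venn counts and the Jaccard
    index of differentially expressed gene sets. A negative-binomial paired
    platform simulator with known ground truth makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    edgeR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
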