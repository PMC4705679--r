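Package: rotsde
Title: Reproducibility-Optimized Test Statistic for Two-Group RNA-Seq
    Differential Expression
Version: 0.1.0
Authors@R:
    person("rotsde", "maintainers", email = "rotsde@example.org",
           role = c("aut", "cre"))
Description: Data-adaptive differential expression testing for two-group
    RNA-seq count data.  The ranking statistic is chosen from a family of
    modified t-statistics by maximizing the bootstrap reproducibility of
    top-ranked gene lists relative to a permutation null (the ROTS
    procedure), with TMM scaling factors and a voom-style log-CPM
    transformation as preprocessing, SAM-style permutation-based false
    discovery rates, a negative-binomial spike-in count simulator with
    known truth, and ROC/confusion evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    edgeR,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
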