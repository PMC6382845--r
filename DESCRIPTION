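Package: stellate
Title: Time-Resolved Cross-Model Analysis of Hepatic Stellate Cell
    Activation Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for time-course RNA-seq of hepatic stellate
    cell (HSC) activation across three experimental models (Western diet,
    carbon tetrachloride, and in vitro transdifferentiation). Implements
    negative-binomial exact-test differential expression, cross-model
    common-gene selection, k-medoids time-course clustering with Pearson
    correlation distance, cluster pairing across models, proximal-promoter
    position-weight-matrix scanning with ZOOPS hypergeometric enrichment,
    and motif-conditional induction statistics. Ships a synthetic-data
    generator that plants known cluster memberships, motif placements and
    effect sizes so every stage of the pipeline can be verified against
    ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    cluster,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
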