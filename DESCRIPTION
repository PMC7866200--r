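Package: tfbsmeta
Title: Rank-Aggregation Meta-Analysis of Differential Expression with
    Promoter TFBS Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Integrates differential-expression result tables from
    heterogeneous transcriptomic studies (RNA-seq, DNA microarray, CAGE)
    into intervention-level differentially expressed gene sets by robust
    rank aggregation, then characterises their upstream regulators:
    strand-aware promoter extraction around the most abundant
    transcription start site, position-weight-matrix scanning with
    empirical site-frequency threshold calibration, transcription-factor
    binding-site enrichment scored by a confidence-interval-corrected
    fold enrichment with exact Fisher tests and FDR control, a
    motif-overlap statistic that quantifies heterodimer evidence, and
    Markov clustering of TF interaction networks. A synthetic-data
    module generates every input with planted ground truth so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
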