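Package: lncoral
Title: Long Non-Coding RNA Discovery and Target Prediction for De Novo
    Transcriptomes
Version: 0.1.0
Authors@R:
    person("lncoral", "maintainers", email = "lncoral@example.org",
           role = c("aut", "cre"))
Description: A stepwise filtering cascade for identifying high-confidence
    long non-coding RNAs (lncRNAs) in de novo assembled transcriptomes of
    non-model organisms such as reef anthozoans, together with two-library
    differential expression (FPKM, Audic-Claverie test, Benjamini-Hochberg
    FDR), hypergeometric pathway enrichment with Bonferroni correction, and
    conserved-region-gated prediction of lncRNA-mRNA interactions by
    intermolecular RNA-RNA duplex energy minimization. A seeded synthetic
    transcriptome generator with a ground-truth manifest makes every stage
    testable at desk scale without external databases or aligners.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    igraph,
    jsonlite,
    methods,
    optparse,
    S4Vectors,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
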