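Package: circReliability
Title: Depletion-Based Reliability Assessment of Circular RNA Candidates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Assesses the reliability of circular RNA (circRNA) candidates
    from paired mock and linear-RNA-depleted (e.g. RNase R treated) RNA-seq
    samples. Implements back-splice junction (BSJ) pseudo-sequence
    construction and junction-spanning read counting, RPM-based treat/mock
    ratio classification into not-depleted and depleted candidates, an
    alignment-ambiguity screen, annotation of identification, conservation,
    biogenesis and function factors, per-factor enrichment testing (Fisher
    exact odds ratios, one-sided Wilcoxon rank-sum tests with effect sizes
    and bootstrap confidence intervals, Benjamini-Hochberg FDR across sample
    pairs), and factor-importance ranking by relative contribution to
    variability explained (RCVE) under a binomial generalized linear model.
    A synthetic-data generator with known ground truth supports end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    BiocGenerics,
    rtracklayer,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
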