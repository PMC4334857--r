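Package: medipdmr
Title: Differential Methylation Analysis for MeDIP-Seq Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for detecting aberrant DNA methylation from MeDIP-Seq
    read data: library-size normalization of binned coverage, per-sample peak
    calling against a locally adaptive (dynamic) Poisson background,
    chi-square testing of candidate differentially methylated regions (DMRs)
    with Benjamini-Hochberg false discovery control and a fold-change gate,
    cross-sample "ultra DMR" consensus on 500 bp genome segments, genomic
    feature and chromosome-band enrichment via odds ratios and Fisher's exact
    test, five-way classification of promoter methylation patterns relative
    to CpG islands and their shores, and integration with gene expression
    through RPKM quantification, a weighted Kolmogorov-Smirnov enrichment
    score with gene-set permutation, and hypergeometric pathway tests. A
    seeded synthetic-data generator plants hyper- and hypomethylated regions
    in chosen genomic features, with coupled expression tables and a
    machine-readable truth table, so every stage is verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    fgsea,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
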