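Package: espanr
Title: Strand-Resolved eSPAN Bias and Replication-Coupled Chromatin Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing strand-resolved chromatin sequencing of
    nascent DNA (eSPAN) around DNA replication origins: fragment-size
    filtering, Watson/Crick separation, per-nucleosome counting and
    log2(Watson/Crick) bias matrices and profiles; MNase-seq
    nucleosome-occupancy metaprofiles with per-region standardization;
    and the phenotype statistics used alongside such experiments
    (silencing-loss rate from flow-cytometry event tables, homologous
    recombination frequency per viable cell, Rad52-focus fractions with
    one-way ANOVA, and soluble-histone immunoblot normalization). A
    synthetic-data generator emulates strand-biased parental and new
    histone deposition at bidirectional replication forks so that every
    stage of the pipeline can be exercised against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    withr
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    jsonlite
Config/testthat/edition: 3
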