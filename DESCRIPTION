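Package: cipkit
Title: Expression Level Polymorphism Discovery from Probe-Level Microarray Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline for deciphering transcriptional divergence between two
    genotypes under a stress treatment from probe-level oligonucleotide array
    intensities. Implements quantile normalization, probe-set summarization
    with target-mean scaling, per-probe balanced two-way ANOVA
    (genotype x treatment with interaction) with Benjamini-Hochberg FDR,
    calling of Core Intersectional Probesets (probe sets with at least three
    member probes significant for all three effects), expression-quadrant
    classification, hypergeometric category enrichment, seed-and-refine de
    novo promoter motif discovery with IUPAC element scanning, probe-vs-genome
    polymorphism screening, and strand-aware InDel-to-gene classification.
    A fully seeded synthetic-data generator with planted effects supports
    end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
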