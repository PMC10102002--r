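Package: tdmdscreen
Title: Screening Target-Directed MicroRNA Degradation Triggers from AGO-CLASH Chimeric Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate triggers of target RNA-directed microRNA
    degradation (TDMD) from AGO-CLASH chimeric sequencing reads. Provides read
    preprocessing (adapter trimming, UMI-based PCR-duplicate collapse), chimera
    splitting and transcriptome mapping of target fragments, an exact
    nearest-neighbor dynamic program for intermolecular miRNA:target duplex
    folding, classification of duplexes against the four structural TDMD
    criteria (seed pairing with G-U wobble, 3'-end supplementary pairing,
    central bulge size, binding energy) and the two abundance/enrichment
    criteria, small-RNA quantification with median-of-ratios normalization,
    target-repression analyses (seed-match prediction, cumulative fold-change
    curves, Mann-Whitney tests, organ-normalized correlation), and a
    synthetic-data generator that emulates CLASH libraries with planted
    triggers and decoys for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    DESeq2,
    withr
Config/testthat/edition: 3
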