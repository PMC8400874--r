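Package: hbdscan
Title: Multiple-Class Hidden Markov Model Analysis of Homozygosity-by-Descent
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-based detection of homozygous-by-descent (HBD) segments from
    diploid SNP-array genotypes. Genotypes are modelled with a hidden Markov
    model whose states are HBD age classes with exponentially distributed
    segment lengths (rates 2..512 per Morgan) plus a non-HBD class. The package
    reads PLINK PED/MAP and BED/BIM/FAM panels, applies call-rate quality
    control, estimates per-individual class mixing proportions by EM, computes
    realized autozygosity and the genomic inbreeding coefficient, decodes HBD
    segments by the Viterbi algorithm, summarises segments per group and class,
    overlaps them with genomic feature intervals, and ships a generative
    simulator for end-to-end validation against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
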