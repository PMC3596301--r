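Package: snoEvol
Title: Evolutionary Analysis of Polycistronic Box C/D snoRNA Gene Clusters
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative-genomic analysis of polycistronic box C/D
    snoRNA gene clusters in fungal-like genomes. Detects box C/D snoRNAs
    (including chimeric fusions) by motif scanning, guide-element scoring and
    family assignment; delineates host introns from canonical splice signals;
    assembles exon/intron cluster architectures and flags complex introns;
    builds cross-species intron presence/absence matrices and classifies
    intron loss-and-gain events by mechanism (de-intronization, genomic
    deletion, excision-and-insertion, recombination, exon loss, intron gain)
    with Fitch parsimony placement on a species tree; detects short direct
    and inverted repeats at insertion junctions; and tests the stepwise
    5'-to-3' splicing hypothesis for complex introns from spliced
    transcripts. Includes a genome-evolution simulator that generates
    synthetic clusters evolved along a phylogeny with a complete ground-truth
    event log, used throughout for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    rtracklayer,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    phangorn,
    S4Vectors,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
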