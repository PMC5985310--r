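Package: iglkit
Title: Immunoglobulin Light-Chain Locus Annotation and Repertoire Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for characterizing immunoglobulin light-chain (IgL) gene loci
    and expressed repertoires in non-model vertebrates. Provides germline V/J/C
    segment annotation on genomic scaffolds with recombination signal sequence
    (RSS) detection and 12/23 vs 23/12 spacer typing, QC and isotype pooling of
    5'-RACE amplicons, V-subfamily clustering at the 75% nucleotide identity
    criterion, V-J junction decomposition into germline, P- and N-nucleotides,
    IMGT-style CDR delineation and length profiling, constant-region expression
    quantification from transcriptome reads, and neighbor-joining p-distance
    phylogenies with bootstrap-supported assignment of sequences to the five
    ancient IgL isotypes (kappa, lambda, sigma, sigma-2, lambda-2). A synthetic
    data module generates germline loci, rearranged cDNAs and reads with full
    ground truth so every stage can be validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors,
    IRanges,
    GenomicRanges,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    rtracklayer
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
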