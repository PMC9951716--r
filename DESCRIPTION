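Package: avissr
Title: Genome-Wide Microsatellite Mining, Characterization and
    Phylogenetically-Informed Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects perfect, imperfect and compound microsatellites
    (SSRs, 1-6 bp motifs) in genome sequences, groups repeat motifs into
    canonical classes under circular permutation and reverse
    complementation, localizes loci in genomic compartments (CDS, exon,
    intron, intergenic) from GFF3 annotation, and computes abundance
    (loci/Mb), density (bp/Mb), repeat-copy-number variability, GC
    content and gene-end positional profiles. Cross-species repeat motif
    preferences are compared with a phylogenetically-informed principal
    component analysis built on the Brownian-motion tree
    variance-covariance matrix. A synthetic-genome simulator with planted
    repeat loci, gene models and known truth tables makes every stage of
    the pipeline testable without external genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phytools,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
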