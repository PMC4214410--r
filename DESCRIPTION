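Package: domestigen
Title: Wild Versus Cultivated Genome Assembly and Domestication Genomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation-backed re-implementation of the computational chain used to
    compare a wild and a domesticated plant genome: redundancy filtering and
    overlap-layout-consensus merging of hybrid contig sets, hierarchical mate-pair
    scaffolding with BAC-end and FPC physical-map guided mega-scaffolding and 500-N
    pseudomolecule emission, k-mer spectrum genome-size and heterozygosity profiling,
    pileup SNV/InDel calling and whole-genome assembly comparison, reciprocal-best
    orthologue matching with NG86 Ka/Ks selection classification, and detection of
    miniature inverted-repeat transposable elements (MITEs) in 1-kb upstream windows
    with association to expression suppression. Includes a seeded synthetic-data
    generator producing diploid wild/cultivar genome pairs, tiered paired reads,
    BAC-end and FPC resources, planted MITEs and negative-binomial expression counts
    with machine-readable truth tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    jsonlite,
    withr,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
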