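Package: tdnascape
Title: Comparative Landscape Analysis of Nuclear tRNA Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processing and comparative analysis of tRNA gene (tDNA)
    annotations across genomes. Reads tRNAscan-SE output, filters
    high-confidence gene sets, tallies isotype and isoacceptor content,
    measures sequence uniqueness and cross-genome identity, calls tDNA
    clusters by interval-density merging, scans flanking regions for RNA
    polymerase III regulatory elements (TATA-box, CAA motif, poly(T)
    terminators), catalogues tRNA introns, partitions cloverleaf secondary
    structures and scores base-pair covariation over structural alignments,
    and reconciles gene trees against species trees to count duplication and
    loss events. A synthetic-genome generator plants all of these features
    with machine-readable ground truth so every stage is testable without
    external assemblies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
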