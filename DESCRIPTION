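Package: reducto
Title: Comparative Genomics of Reductive Evolution in Lactic Acid Bacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to characterise reductive genome evolution in closely
    related bacterial strains, modelled on the comparison of Lactobacillus
    delbrueckii ssp. lactis and ssp. bulgaricus: all-vs-all protein
    comparison with single-linkage ortholog clustering and core/pan-proteome
    partitioning, pseudogene-fragment detection by translated search and
    genomic back-alignment, genome composition statistics (GC, GC3, coding
    density, IS-element landscape), marker-gene and MLST phylogenetics with
    neighbor joining, bootstrap and Robinson-Foulds incongruence screening
    for horizontal transfer, diagnostic-site detection, and carbohydrate
    pathway-completeness phenotype prediction.  A synthetic-genome generator
    evolves strain genomes from a planted ancestral pangenome (gene loss,
    pseudogenisation, IS insertion, horizontal acquisition) with
    machine-readable ground truth so that every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    ape,
    data.table,
    stats,
    utils,
    methods,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    phangorn,
    withr
Config/testthat/edition: 3
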