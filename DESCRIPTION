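Package: vitring
Title: Circular Phylogenetic Profiling of Microbial Communities from 16S
    rRNA Gene Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale toolkit for 16S rRNA gene based taxonomic
    profiling of microbial communities from amplicon or metagenomic
    shotgun reads.  Curates a phylogenetically non-redundant 16S
    reference set (anchor-motif trimming, length and homopolymer
    filters, greedy centroid clustering), lays reference taxa on a
    circle by scanning the topology of a neighbor-joining tree built
    from Kimura two-parameter distances, classifies reads with a k-mer
    seed-and-extend identity search against a prebuilt index, normalizes
    genus abundances by inferred 16S gene copy number, reconstructs
    nearly full-length 16S genes from shotgun reads by greedy
    overlap-consensus assembly, and compares samples with Jaccard,
    Pearson and Yue-Clayton theta statistics.  Includes a synthetic-data
    generator (random trees, sequence evolution under the Kimura model,
    mock-community read simulation) so the whole pipeline is testable
    without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
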