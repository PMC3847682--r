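Package: polygenespace
Title: Gene-Space Assembly and Copy-Number Estimation for Repeat-Rich
    Polyploid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing shotgun survey sequence of large,
    repeat-rich (allo)polyploid genomes without a contiguous assembly.
    Sequencing reads are allocated to orthologous group representative
    (OGR) proteins by translated alignment, sub-assembled per gene bin
    with a stringent minimum overlap identity, and gene copy numbers
    are estimated from position-specific hit-count profiles of the
    sub-assemblies along each template protein.  Includes seeded
    simulators for the two calibration experiments (a diploid
    whole-genome shotgun run and an in-silico polyploid gene
    catalogue), Markov clustering of protein similarity graphs for
    ortholog group construction, a similarity-based sub-genome
    classifier with probability-threshold rejection, and a
    synteny-driven virtual gene-order ("zipper") builder that anchors
    sequences along a genetic marker backbone.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    data.table,
    e1071,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    nnet,
    rpart
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
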