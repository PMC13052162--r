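Package: ednadivide
Title: Inter- and Intraspecific Diversity of Riverine Fish from eDNA Metabarcoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for deriving inter- and intraspecific
    diversity patterns of riverine fish communities from denoised eDNA
    metabarcoding ASV tables. Implements negative-control contamination
    subtraction, occurrence and read-count filtering, a stop-codon (NUMT)
    screen under the vertebrate mitochondrial code, marine-family exclusion
    and basin-level pooling; genetic-distance-weighted between-community mean
    pairwise distance (betaMPD); conductance-raster least-cost-path landscape
    distances; Jaccard/PCoA/ANOSIM/Mantel community statistics; and
    generalized dissimilarity models with monotone I-splines to test
    isolation by distance. A synthetic riverscape and haplotype generator
    with known ground truth makes every stage testable without sequencing
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    igraph,
    geosphere,
    pracma,
    jsonlite,
    ape,
    seqinr,
    vegan,
    Rcpp
LinkingTo: Rcpp
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    picante,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
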