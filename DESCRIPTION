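Package: strucphylo
Title: Assembly of Structural Phylogenetics Datasets from Protein Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds datasets for structure-based phylogenetics from directories
    of protein structures. Splits multi-chain PDB entries into per-chain records,
    filters them by deposited sequence length, clusters them greedily at a
    sequence-identity threshold, designates and vets cluster centroids, compares
    centroid structures with a Qscore-based secondary-structure-seeded rigid
    aligner, compares centroid sequences with BLOSUM62 local alignment
    statistics, and exports ranked structural neighbourhoods, NEXUS-formatted
    distance matrices (distance = 1 - Qscore) and neighbour-joining trees.
    Includes a deterministic synthetic-structure generator (ideal helices,
    strands, random-coil walks, mutated and perturbed copies) so the whole
    pipeline can be exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    bio3d,
    Biostrings,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
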