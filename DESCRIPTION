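Package: rinmut
Title: Residue Interaction Networks and Structural Context for Point Mutations
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Batch structural characterization of point mutations in a
    protein chain. Builds atomic and residue-level interaction networks
    from Delaunay-filtered interatomic contacts classified by
    physicochemical distance criteria (hydrogen bonds, salt bridges,
    aromatic stacking, hydrophobic, repulsive and disulfide contacts),
    computes network centralities (degree, betweenness, closeness) and
    Lee-Richards solvent accessibility in the ten Naccess-style
    categories, assembles a structure-based family alignment against the
    wild-type chain, and aggregates per-column conservation, property
    statistics and interaction conservation to assess the
    conservativeness and likely structural impact of point substitutions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    igraph,
    Biostrings,
    mclust,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
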