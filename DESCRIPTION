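Package: MolTopo
Title: Combinatorial SMILES Libraries, Topological Descriptors and QSAR
    Screening
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds combinatorial molecular libraries from SMILES-encoded
    scaffolds with anchor points and per-position substituent lists, computes
    topological and graph-theoretic descriptors from the hydrogen-suppressed
    molecular graph (Kier-Hall connectivity indices with valence variants and
    quotient/difference combinations, Galvez topological charge indices, the
    Wiener index, constitutional counts, the hyper-detour index, MAXDN,
    Burden-matrix eigenvalue descriptors and adjacency eigenvector sums), and
    evaluates linear discriminant and regression QSAR models with an
    applicability window to screen libraries for predicted activity. Includes
    generic LDA/MLR fitting machinery with leave-one-out cross-validation and
    response scrambling, pharmacological distribution diagrams, readers for
    SMILES/Molfile/SDF input, a two-part descriptor table writer and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    yaml,
    withr,
    MASS,
    ChemmineR,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
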