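Package: osmkit
Title: One-Step Mutation Matrices and Minimal Substitution Counts on Rooted Phylogenies
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the one-step-mutation (OSM) framework in molecular
    evolution: Abelian permutation groups acting regularly on character-state
    alphabets (Klein four-group / K3ST, cyclic and direct-product groups up to
    amino-acid alphabets), their Kronecker lift to whole alignment columns on
    a rooted binary phylogenetic tree with a degree-1 root, the sparse doubly
    stochastic OSM matrix and its Cayley graph, a proven Fitch-based
    computation of the minimal number of substitutions transforming one
    alignment column into another, and Birkhoff-von Neumann audits of
    substitution models against the group conditions the framework requires.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    igraph,
    jsonlite,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
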