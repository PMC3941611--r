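Package: betaACV
Title: Beta-Contact Graphs and ASA-Weighted Atomic Contact Vectors for
    Alanine-Scanning Binding Free Energy Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds beta-contact graphs of protein quaternary structures
    (Delaunay/Voronoi adjacency, van der Waals distance cutoff and
    beta-skeleton forbidden-region filtering), computes per-atom solvent
    accessible surface areas and local burial terms in bound and unbound
    states, assembles 52-element atomic-contact-vector features for
    interfacial alanine mutations (with bound-water handling), and predicts
    binding free energy changes and binding hot spots by ridge regression
    with leave-one-out cross-validation. Includes seeded synthetic fixture
    generators (atom clouds, toy two-chain complexes, linear-response
    mutation datasets) and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
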