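Package: geofold
Title: Geometric-Constraint Folding of Sphere Chains and Protein Residue
    Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the compaction of a chain of sticky hard spheres in
    which randomly chosen pairs of units are joined whenever volume exclusion
    and previously formed links geometrically permit, and compares the
    resulting contact networks with protein residue networks built from
    C-alpha coordinates by distance thresholding. Provides network and
    geometric observables (degree statistics, graph diameter, radius of
    gyration, graph-Laplacian spectra) and power-law scaling fits of
    aggregate extent against chain length, together with deterministic
    synthetic fixtures and a small command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    bio3d,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
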