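Package: hyperdm
Title: Disease Modules in the Hyperbolic Geometry of Protein Interaction Networks
Version: 0.1.0
Authors@R: person("Maintainer", "Dev", email = "dev@example.org", role = c("aut", "cre"))
Description: Tools to study disease modules on protein interaction networks
    embedded in the two-dimensional hyperbolic plane. Provides the core
    hyperbolic-plane mathematics (distances, Fermi-Dirac connection
    probabilities, expected degrees, disk-radius calibration), a static
    popularity-similarity model generator with ground-truth coordinates,
    manifold-learning plus likelihood-refinement coordinate inference with a
    four-criterion embedding evaluation, disease-module fragmentation
    statistics against uniform sampling nulls, hyperbolic and shortest-path
    module-separation measures with minimum curvilinear embedding, Ward
    clustering and a concordance score, greedy-routing navigability
    experiments with faulty-protein injection, and angular protein-class
    enrichment. A synthetic-data module emulates all required inputs so the
    full pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    Rcpp,
    stats,
    utils,
    data.table,
    jsonlite,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
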