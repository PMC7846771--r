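Package: methylsat
Title: Exhaustive Methyl NMR Resonance Assignment by Satisfiability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Exact, exhaustive enumeration of methyl-TROSY NMR resonance
    assignments for large proteins. Starting from a raw 2D 1H-13C HMQC
    reference peak list, two 3D Cm-CmHm NOESY peak lists (short and long
    mixing time) and a 3D structure or model ensemble, the assignment
    problem is cast as a subgraph isomorphism of the NOE-derived data
    graph into a structure-derived methyl connectivity graph and reduced
    to Boolean satisfiability. A built-in conflict-driven clause-learning
    solver enumerates, for every reference peak, the complete support set
    of methyls compatible with all experimental constraints: NOE network,
    residue types, stereospecificity, geminal connectivities and partial
    assignments. Includes chemical-shift residue-type classification, a
    ground-truthed synthetic benchmark simulator, and a command-line
    front-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    optparse
Config/testthat/edition: 3
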