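Package: xiosfp
Title: Topological Fingerprints for RNA Secondary Structures with Pseudoknots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Represents RNA secondary structures, including pseudoknots, as
    XIOS stem-relationship graphs in which vertices are helices (stems) and
    labeled edges record whether two stems are nested (I), pseudoknotted (O)
    or mutually exclusive (X); serial stems carry no edge. Provides parsers
    for CT, BPSEQ and extended dot-bracket formats, exhaustive enumeration of
    all unique IO-connected stem topologies of up to seven stems indexed by a
    canonical graph code, determination of the motif spectrum (fingerprint)
    of a structure by random connected-subgraph sampling or exhaustive
    enumeration, set-based fingerprint similarity functions, and evaluation
    utilities (ROC/AUC, neighbour-joining clustering, vertex-removal and
    decoy graph-expansion protocols) together with a synthetic topology
    generator for simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    ape,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
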