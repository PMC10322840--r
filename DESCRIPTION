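Package: ksrtools
Title: Comparative Sequence Analysis of RAF and KSR-Family Pseudokinases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of RAF kinases and the
    catalytically inactive KSR (Kinase Suppressor of Ras) scaffold family,
    with emphasis on KSR3-type pseudokinases: kinase-domain motif
    fingerprinting (P-loop, VAIK, HRD, DFG, dimerization and 14-3-3 motifs,
    C1/CRD and accessory domains), architecture-based RAF/KSR1-2/KSR3
    classification corroborated by neighbor-joining trees with bootstrap
    support, per-position divergence profiling of a pseudokinase set against
    a reference kinase, and homology-guided transposition of family-specific
    residues onto an acceptor kinase to nominate candidate activating
    mutations. Includes affine-gap pairwise alignment with bidirectional
    residue-coordinate liftover and a synthetic-sequence generator with
    ground truth for benchmarking every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    optparse
Config/testthat/edition: 3
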