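Package: prsdyn
Title: Perturbation Response Scanning and Dynamic Coupling Analysis of Protein Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained analysis of protein conformational dynamics built on
    perturbation response scanning over an elastic network model or an externally
    supplied covariance matrix. Computes per-residue dynamic flexibility (DFI) and
    dynamic coupling (DCI) indices with percentile ranks, coupling asymmetry,
    mutational delta-profiles, and identifies dynamic allosteric residue coupling
    (DARC) sites. Includes a trajectory-to-covariance adapter with moving-window
    averaging, SVD-based hierarchical clustering of variant flexibility profiles,
    a feed-forward neural-network pathogenicity classifier over dynamics features,
    and seeded synthetic-structure generators for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
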