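Package: fragalign
Title: Fragment-Seeded Protein Structure Alignment and Database Search
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pairwise and one-against-all protein structure alignment from
    alpha-carbon traces. Alignments are seeded by matched sets of backbone
    fragments, assembled by dynamic programming at fragment and residue
    level, refined by iterative maximal-subset superposition driven by a
    quaternion characteristic polynomial (QCP) rigid-body engine, and
    assessed with TM-score, percentage of structural similarity (PSI), a
    length-calibrated z-score, and RMSD100. Includes synthetic structure
    generators (ideal helices, perturbed and rigidly moved copies,
    random-walk decoys) so the whole pipeline is testable without external
    data, plus a small command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
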