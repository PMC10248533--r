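Package: Get3Atlas
Title: Desk-Scale Phylogenomics and Structure Comparison of the Get3/ArsA
    Family
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable pipeline for tracing Get3/ArsA subfamilies
    (including the chloroplast Get3d subfamily) across photosynthetic
    bacteria and plants at desk scale: profile-based harvesting of
    Get3/ArsA-like monomer domains with pseudodimer splitting and
    alpha-crystallin-domain flagging, greedy identity clustering with
    paired-half retention, seed-anchored progressive alignment with
    keep-length addition, maximum-likelihood phylogenetics under empirical
    amino-acid models (Felsenstein pruning, branch-length optimization,
    NNI search, nonparametric bootstrap, support collapse, likelihood-based
    evolutionary placement, MRCA rooting), anchor-based clade assignment
    with genus-level presence/absence mapping, and quantitative structure
    comparison (Kabsch superposition RMSD, Shrake-Rupley solvent-accessible
    surface area and interface burial, salt-bridge and cis-peptide
    detection, Kyte-Doolittle hydrophobicity, grid-based cavity volume).
    Includes a seedable synthetic-data generator for gene families evolving
    by duplication, loss, domain fusion and accessory-domain gain so every
    stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    Biostrings,
    ape,
    phytools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    Matrix,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
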