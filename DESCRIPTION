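Package: rmsdclust
Title: Radial- and Diametral-Threshold Clustering of Molecular Conformations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Conformational clustering of molecular-structure ensembles using
    the pairwise root-mean-squared difference (RMSD) of Cartesian coordinates
    as the similarity metric. Implements the two classic iterative
    maximal-neighborhood algorithms: radial-threshold clustering (RTC), where
    membership is decided by the RMSD from the cluster seed, and
    quality-threshold clustering (QTC), where every pair of members must
    satisfy a diametral threshold so cluster diameters are bounded. Also
    provides optimal least-squares (Kabsch) superposition, pairwise RMSD
    matrix construction with a text/binary cache format, diagnostics for
    choosing a physically meaningful radial threshold from per-seed RMSD
    distributions, cluster-geometry summaries (diameter, radius of gyration,
    seed-to-centroid distance, seed-pair angles), coverage statistics, and
    reproducible synthetic ensemble generators with planted cluster structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
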