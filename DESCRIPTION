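Package: loopscape
Title: Conformational Clustering and Mapping of Protein Loop Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of short-loop conformational dynamics in molecular
    dynamics trajectories of immunoglobulin-like receptor domains.
    Implements framework-fitted root-mean-square deviation and fluctuation
    statistics for a loop of interest, greedy RMSD-cutoff (neighbor-count)
    conformational clustering with central-structure extraction, non-metric
    multidimensional scaling of cluster representatives, automated
    meta-cluster delineation by average-linkage grouping, per-system
    occupancy and residence-time accounting, and cluster-count convergence
    diagnostics over growing trajectory prefixes. Includes a synthetic
    trajectory generator that plants template loop conformations switched
    by a Markov process, so every stage of the pipeline can be validated
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
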