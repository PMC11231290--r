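Package: clustric
Title: Temporal Patient Stratification by Triclustering and Hierarchical
    Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Stratifies patients into disease-progression groups from
    longitudinal clinical assessments. Irregularly timed assessments are
    aligned into appointment snapshots and assembled into a three-way
    (patient x feature x appointment) dataset; temporally contiguous,
    ratio-coherent triclusters are mined from the cube; each tricluster is
    summarised by a 3D virtual pattern; patients are embedded as Euclidean
    distances to every pattern at every appointment; and Ward-linkage
    hierarchical clustering of that embedding yields progression groups.
    Includes cluster-validity indices for choosing the number of groups,
    per-group trajectory characterisation, Kaplan-Meier/log-rank survival
    validation, and a seeded generator of synthetic ALS-like cohorts with
    planted progression groups for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    survival,
    cluster,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
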