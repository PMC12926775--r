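Package: clusterscan
Title: Longitudinal Cortical Atrophy Analysis for Cluster-Scanned Structural MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for detecting short-interval longitudinal cortical atrophy
    from densely repeated ("cluster-scanned") structural MRI morphometrics.
    Implements W-score normative modeling of cortical thickness against a
    control cohort, individualized core-atrophy and control region-of-interest
    construction on a surface mesh, rigid-body RMS-displacement motion quality
    control, restricted maximum likelihood mixed models with nested random
    intercepts and stratified residual variances, estimated marginal means with
    pairwise and interaction contrasts, vertex-wise change maps with a
    singular-fit fallback cascade, and bootstrap precision curves with a
    diminishing-returns scan-count rule. A synthetic-data module generates
    datasets with known ground truth emulating a three-timepoint,
    32-scans-per-timepoint study design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    nlme,
    emmeans,
    optparse
Config/testthat/edition: 3
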