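Package: richclubnet
Title: Rich-Club and Graph-Theory Analysis of FA-Weighted Structural Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <maintainer@example.org>
Description: Builds fractional-anisotropy (FA) weighted structural brain
    networks from streamline summaries, computes global and nodal
    graph-theory metrics with degree-preserving null models, identifies
    rich-club hub regions and abnormal hub-hub connections between
    clinical groups, maps connections onto resting-state networks, and
    relates network metrics to clinical variables with covariate-adjusted
    statistics. Includes a synthetic-cohort generator with planted hub
    structure and group effects so every stage of the pipeline can be
    exercised and validated without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
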