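Package: emfi
Title: Divide-and-Conquer EM-FI Solver for Large-Scale p-Median Problems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Solves weighted p-median facility-location problems with a
    density-based divide-and-conquer strategy: demand points are decomposed
    into spatial clusters with a bivariate Gaussian mixture model selected by
    BIC, non-clustered (sparse or homogeneous) subregions are dissolved into
    dense ones using a quadrat chi-squared homogeneity test, facilities are
    apportioned to subregions in proportion to demand, and the subproblems
    are solved concurrently by exact branch-and-bound or the fast-interchange
    (vertex substitution) heuristic. Conquer steps reassign destinations
    globally and optionally refine the solution by global fast interchange or
    by iterative distance-based re-decomposition of the current facilities
    (k-means partitions scored by the Davies-Bouldin index). Includes a
    synthetic instance generator for clustered, centered, and homogeneous
    demand surfaces, CSV/JSON/GeoJSON input-output, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    parallel,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
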