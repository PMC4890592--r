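Package: residualscope
Title: Projected and Residual Subspace Analysis of Expression Compendia
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying the linear structure of large, heterogeneous
    gene-expression compendia. Decomposes a log2-scale expression matrix into
    the subspace spanned by the first k principal components ("projected") and
    its orthogonal complement ("residual"), and quantifies how two-group
    differential-expression evidence partitions between the two subspaces via
    an information-ratio statistic. Includes group-signature correlation
    analysis before and after decomposition, principal-component analysis of
    residual sample subsets with external validation, proportion-matched
    downsampling and sample-size perturbation scans, kurtosis-based screening
    for bimodally expressed genes, projection onto predefined biological
    direction sets, and a synthetic-data generator with ground truth that
    emulates the cluster, minority-group, few-gene, batch and noise structure
    of real compendia.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
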