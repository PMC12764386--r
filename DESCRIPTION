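Package: gpsclust
Title: Gaussian Process Spatial Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Model-based clustering for supervised spatial data in which
    observations carry a planar location, a covariate vector and a scalar
    response, and each latent cluster is governed by a distinct unknown
    response function. Each cluster's function is approximated by a
    Gaussian process with a squared exponential kernel fitted by bounded
    maximum marginal likelihood, and observations are iteratively
    reassigned to the cluster whose predictor explains their response
    best, optionally penalised by distance to the cluster's spatial
    center. Includes synthetic spatial study designs with known labels,
    adjusted Rand index and adjusted mutual information for evaluation,
    CSV input/output and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
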