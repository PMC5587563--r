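Package: connectopy
Title: Group Analysis of Weighted Structural Brain Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Construction and group-level statistical analysis of weighted
    structural connectomes. Builds volume-normalised, symmetric connectivity
    matrices from streamline counts, thresholds them to fixed edge densities
    using a pooled group-median summary matrix, and computes weighted graph
    measures (global and local efficiency, weighted clustering, modularity,
    node strength) with normalisation against degree- and strength-preserving
    randomised reference networks. Group inference uses max-statistic
    permutation tests for connectivity strength quartiles and a
    multi-threshold cluster permutation (MTCP) procedure based on the
    supercritical area-under-the-curve of t-statistic curves across edge
    densities. Includes association of network measures with clinical
    severity scores (linear, rank and age-partial correlations; linear versus
    exponential model comparison by small-sample AIC) and a synthetic
    connectome cohort generator with known ground truth for calibration and
    power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
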