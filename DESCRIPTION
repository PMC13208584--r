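Package: msieval
Title: Ion Filtering and Dual-Metric Evaluation of Spatial Clustering for Mass Spectrometry Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality-filters mass spectrometry imaging (MSI) peak-intensity
    matrices by a per-ion Spatial Noise Score (SNS) and evaluates pixel
    clusterings with a dual-metric framework: spatial continuity via the
    Percentage of Abnormal Spots (PAS) and inter-cluster metabolic
    heterogeneity via the median of per-ion eta-squared values. Includes
    normalized mutual information for consistency and external validation,
    one-vs-rest Moran's I summaries, reference clustering baselines
    (PCA followed by k-means, Gaussian mixtures or Ward agglomeration),
    a synthetic phantom generator with planted spatial regions, and an
    orchestrated filter-cluster-evaluate-rank pipeline with CSV/JSON
    outputs and ggplot2 figures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mclust,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    cluster,
    optparse,
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
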