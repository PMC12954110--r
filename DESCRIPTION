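Package: aoclust
Title: Average-Overlap Comparison, Merging and Annotation of Single-Cell Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative comparison of unsupervised single-cell RNA-seq
    clusters from their ranked marker-gene lists using the top-weighted
    average overlap (AO) statistic. Provides one-vs-rest Wilcoxon marker
    ranking, a permutation null for calibrating AO z-scores, AO-distance
    hierarchical clustering of clusters with z-score-guided iterative
    merging, a benchmarking harness (adjusted Rand index, adjusted mutual
    information, Fowlkes-Mallows score, cluster purity, centroid expression
    distances, correlation/Euclidean/direct-overlap baselines, Stouffer
    composite-z reference mapping) and a negative-binomial synthetic-data
    generator with planted marker blocks for truth-known evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ape,
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
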