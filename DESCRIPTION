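Package: koclust
Title: Functional Clustering of Metagenome KEGG-Ortholog Abundance Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing environmental metagenomes through their
    KEGG-ortholog (KO) gene-abundance profiles. Implements sample quality
    filtering of assembled-metagenome profiles, centered log2-ratio
    normalization of the compositional count matrix, unsupervised clustering
    (k-means and Ward hierarchical) with bootstrap model selection scored by
    average silhouette and adjusted Rand index, permutation-validated
    identification of cluster-specific marker orthologs via Kruskal-Wallis and
    Dunn post-hoc tests with median log2 fold-change thresholds, KEGG pathway
    roll-ups of marker sets, and regression of per-ortholog abundance on
    community GC content. A synthetic-data generator with planted cluster,
    marker and GC structure supports end-to-end validation, and a configurable
    pipeline driver orchestrates all stages with provenance tracking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
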