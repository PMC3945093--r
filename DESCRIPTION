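Package: mqtlmap
Title: Metabolite QTL Mapping in a Haploid Yeast Cross
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Linkage mapping of metabolite abundance traits in a haploid
    two-parent yeast cross. Provides preprocessing of replicated LC-MS ion
    counts (detection flooring, detection-rate filtering, optical-density
    normalization, same-day reference log-ratios), parental-difference and
    mode-of-inheritance analysis, single-marker LOD genome scans (normal and
    nonparametric models) with per-trait permutation thresholds and Bayesian
    credible intervals, Poisson-binned linkage hot-spot detection, genomic
    interval permutation enrichment of annotated genes, broad-sense
    heritability and per-QTL variance partitioning from biological
    replicates, and a synthetic-data generator emulating a densely
    genotyped haploid cross.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
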