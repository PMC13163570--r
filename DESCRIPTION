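Package: lactatlas
Title: Multi-Tissue Expression Atlas Screening and Lactation Trait Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Screening toolkit for multi-tissue bulk RNA-seq atlases of dairy
    livestock. Identifies housekeeping genes by coefficient-of-variation
    quartile classification crossed with expression-abundance bins, calls
    tissue-, marker- and lactation-stage-specific genes by a fold-ratio rule
    after group-aware smooth quantile normalization, ranks candidate qPCR
    reference genes with from-scratch implementations of geNorm, NormFinder,
    BestKeeper, the comparative delta-Ct method and their RefFinder-style
    geometric-mean aggregation, clusters stage expression trends by fuzzy
    c-means and matches cluster centroids to lactation-trait trajectories,
    and analyses milk yield and composition records (Spearman correlations,
    stage comparisons). Seeded simulators with planted ground truth make
    every stage of the pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), e1071, limma, jsonlite, optparse, withr,
    knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
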