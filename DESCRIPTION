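Package: chassisconcord
Title: Pangenome-Aware Analysis of Genetic Device Performance Across
    Bacterial Hosts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the chassis-effect: host-dependent variation in the
    performance of an identical genetic device across bacterial species.
    Partitions a pangenome into core, accessory and unique gene clusters,
    tests COG-category enrichment per frequency group, estimates device
    performance and growth metrics from plate-reader curves (Hill induction
    fits, Gompertz growth fits with lag, rolling-regression maximum rates),
    runs a negative-binomial Wald differential-expression stage on
    cluster-pooled RNA-seq counts, and tests concordance between each
    host's expression response and its device performance by Procrustes
    superimposition with a permutation (PROTEST) null. Ships a synthetic
    study generator with planted ground truth for validation of every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
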