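Package: plasmodeBench
Title: Plasmode and Simulation Benchmarks for RNA-Seq Differential
    Expression Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Generates ground-truth RNA-seq count datasets in two
    complementary ways, by parametric over-dispersed (lognormal-)Poisson
    simulation and by model-free plasmode construction from a base
    dataset (sample reshuffling, within-block randomization and binomial
    thinning spike-ins), and evaluates differential-expression testing
    procedures for type-I error calibration and power. Includes
    self-contained re-implementations of the compared engines: negative
    binomial GLM likelihood-ratio tests with tagwise-shrunk or
    trend-maximum dispersions, and gene-wise and moderated F-tests on
    log2-CPM values with tabulated or permutation p-values, plus
    filtering, TMM and median-of-ratios normalization, and truth-aware
    scoring (confusion counts, ROC and type-I error curves, uniform Q-Q
    data, p-value histograms).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    edgeR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
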