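Package: regioglia
Title: Regional Stress-Response Analysis of Single-Cell RNA-Seq Data
Version: 0.1.0
Authors@R:
    person("Regioglia", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for quantifying regional
    differences in cellular stress responses from single-cell RNA-seq
    data. Implements per-cell-type Alteration Scores built from
    expression and detection-proportion fold changes of signature genes,
    graph heat-kernel estimation of per-cell condition-associated
    relative likelihoods with three-way change classification,
    cell-level quality control and doublet detection via artificial
    doublets, Wilcoxon rank-sum differential expression with
    fold-change-based regional categorization, and a negative-binomial
    synthetic-data generator with planted ground truth for validating
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    withr
Config/testthat/edition: 3
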