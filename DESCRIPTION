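Package: txpod
Title: Transcriptomic Benchmark Dose Modeling and Point-of-Departure Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Benchmark dose (BMD) analysis of multi-platform dose-response
    gene-expression studies. Implements present/absent calls and ANOVA/FDR
    pre-filtering of expression matrices, per-gene continuous dose-response
    modeling (linear, polynomial, power, Hill) with BMDExpress-style model
    selection and a benchmark response of 1.349 control standard deviations,
    profile-likelihood BMDL lower bounds, quantal (dichotomous) modeling of
    differentially-expressed-gene counts at 10% extra risk, pathway-level
    BMD aggregation over GMT gene sets, four point-of-departure selection
    strategies, and cross-platform concordance statistics. A synthetic-data
    generator with known ground truth emulates microarray, RNA-seq and qPCR
    studies for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
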