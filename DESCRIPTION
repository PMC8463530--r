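Package: targetmr
Title: Drug-Target Mendelian Randomization and Compound-Stratified Trial Meta-Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cis-instrument drug-target Mendelian randomization with
    correlated instruments: reading and harmonizing GWAS summary statistics,
    cis-window extraction, minor-allele-frequency and F-statistic instrument
    filters, greedy LD clumping, generalized-least-squares inverse-variance
    weighted estimation (univariable and multivariable), leverage/outlier
    pruning and heterogeneity diagnostics. Companion machinery for
    compound-stratified meta-analysis of randomized trials (fixed and
    DerSimonian-Laird random effects, between-compound Cochran Q,
    meta-regression, funnel coordinates) and for direction-signed
    -log10(p) evidence matrices with hierarchical clustering, so genetic
    target effects can be compared with drug-compound effects. Includes a
    synthetic-data generator producing two-sample summary statistics with
    autoregressive linkage disequilibrium, configurable mediation, a
    reference dosage panel, and multi-compound trial datasets, making the
    whole pipeline testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
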