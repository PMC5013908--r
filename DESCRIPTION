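Package: wincurse
Title: Winner's Curse Correction for Genome-Scan Z-Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the true means (noncentralities) of genome-scan
    Z-scores, correcting the winner's curse bias that inflates the most
    significant association statistics. The core method, FDR inverse
    quantile transformation (FIQT), adjusts two-sided p-values for multiple
    testing with the Benjamini-Hochberg procedure and back-transforms the
    q-values to the signed Z-score scale. Comparator estimators are
    included: Tweedie's-formula empirical Bayes shrinkage fitted by
    smoothed Poisson regression of binned counts (with an interleaved
    subset extension for locally correlated statistics), conditional
    maximum likelihood tail adjustment for statistics exceeding a selection
    threshold, and the naive estimator. A genome-scan simulator with
    ARMA-correlated residuals mimicking linkage disequilibrium, an
    evaluation harness (cumulative MSE, R-squared, bias and variance over
    p-value thresholds), and utilities to predict which sub-threshold
    signals will reach genome-wide significance in larger future cohorts
    round out the toolkit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    splines,
    data.table,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
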