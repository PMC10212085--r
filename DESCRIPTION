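Package: curlipulse
Title: Single-Cell Analysis of Bimodal and Pulsatile Curli Reporter Activation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying stochastic, pulsatile activation of the
    curli (csgBAC) reporter in Escherichia coli at single-cell resolution.
    Provides a stochastic telegraph-model generator of mother-machine lineage
    traces and flow-cytometry-like endpoint samples; estimators for
    instantaneous growth rate, threshold-crossing times, maximal induction
    rate, first-peak amplitude and post-peak decay half-time with explicit
    censoring; threshold-aligned median expression profiles; kernel density
    estimates of log-fluorescence; fixed-gate and Gaussian-mixture based
    quantification of the curli-positive fraction with replicate summaries;
    and Welch's unequal-variance t-test for between-strain comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    parallel,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
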