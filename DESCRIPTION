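Package: gentriflow
Title: Redlining, Gentrification and Socio-Spatial Residential Mobility
    Analysis of Tract Life Expectancy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to study how neighborhood gentrification status and
    household residential mobility modify the association between
    historical HOLC (Home Owners' Loan Corporation) redlining grades and
    census-tract life expectancy at birth. Implements a Sutton-style
    composite gentrification index with two classification windows, a
    household mobility-flow classifier producing per-tract net changes in
    lower-, moderate- and higher-income households with quartile-based
    magnitude categories, population-weighted life-expectancy summaries,
    HOLC-stratified linear models (unadjusted and mobility-adjusted), and
    a Bayesian spatial regression with an intrinsic conditional
    autoregressive (ICAR) smoothing term and credible-interval tract
    flagging. A synthetic metropolitan-area generator with known ground
    truth stands in for proprietary household trace data and restricted
    tract-level inputs so the whole pipeline is reproducible and testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
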