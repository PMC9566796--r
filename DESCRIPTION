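Package: swotahp
Title: Quantitative SWOT Analysis with the Analytic Hierarchy Process
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantitative SWOT (strengths, weaknesses,
    opportunities, threats) strategic analysis built on the analytic
    hierarchy process (AHP).  Validates Saaty pairwise-comparison
    matrices, derives priority weights by the sum-product (column
    normalisation and row averaging) method, runs the lambda-max /
    CI / CR consistency test, combines weights with expert-scored
    signed intensities into group strengths, and locates the
    resulting strategy on the SWOT quadrilateral via its centroid,
    azimuth, zone, and strategic intensity coefficient.  Includes
    Delphi-style expert-panel aggregation, a synthetic panel
    generator with controlled judgment noise for Monte-Carlo
    sensitivity analysis, and an end-to-end pipeline runner with
    JSON and text reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
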