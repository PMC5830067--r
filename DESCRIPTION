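Package: plscm
Title: Partial Least-Squares Class Modeling for Immunophenotype Case-Control Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Two-stage partial least-squares class modeling (PLS-CM) for
    high-dimensional percentage data such as flow-cytometry immunophenotype
    panels. Fits univariate-response NIPALS PLS on uncentered data, selects
    variables by their influence on projection (VIP), models the per-class
    distribution of the calculated response with normal densities, derives
    type I/II risk curves and the equal-error sensitivity/specificity
    operating point, searches rotated two-component score projections for a
    separating vertical line, and provides Mann-Whitney univariate screens
    plus CD4-slope case/control classification. A synthetic cohort generator
    with planted effects makes every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics
Config/testthat/edition: 3
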