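Package: cisir
Title: Coordinate-Independent Sparse Sliced Inverse Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sufficient dimension reduction with simultaneous variable
    selection for high-dimensional regression and classification. Estimates a
    row-sparse basis of the central subspace by a convex group-Dantzig
    program seeded by sliced inverse regression, with constrained l1
    (CLIME) precision-matrix estimation for the p >= n regime, data-driven
    tuning by cross-validated misclassification or a BIC-type criterion,
    nearest-centroid prediction on the sufficient predictors, and a
    simulation suite with known truth for benchmarking selection,
    estimation, and prediction accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    boot,
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
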