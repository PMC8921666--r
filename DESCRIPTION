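Package: radbench
Title: Benchmarking Gene-Expression Signatures of Cellular Radiosensitivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Evaluates gene-expression signatures as predictors of cellular
    radiosensitivity (surviving fraction at 2 Gy or mean inactivation dose)
    against size-matched resampled-control signatures and an intercept-only
    null model. Provides principal components regression, rank-based linear
    and partial-least-squares/support-vector model families behind one
    fit/predict contract, a paired cross-validation engine with
    per-cell-line absolute errors, two one-sided tests (TOST) equivalence
    testing against median-accuracy controls, tissue-stratified error
    analyses, linear-quadratic survival endpoints, and a synthetic
    radiogenomic data generator so the whole workflow runs with no external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    pracma,
    e1071,
    mixOmics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    jsonlite
Config/testthat/edition: 3
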