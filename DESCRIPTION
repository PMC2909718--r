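Package: poolsim
Title: Simulating Pooled-Sample Designs for Gene-Expression Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A simulation framework for quantifying how RNA sample pooling
    degrades two-group classification of gene-expression biosignatures.
    Generates two-class log2-scale expression matrices under three scenarios
    (independent differentially expressed genes, bivariate linear patterns,
    and their combination), applies an ideal raw-scale pooling operator to
    training sets, trains five classifiers (linear and radial support vector
    machines, random forests, a from-scratch powered partial least squares
    discriminant analysis, and t-test feature selection followed by linear
    discriminant analysis), and evaluates prediction error on independent
    single-sample test sets over many Monte-Carlo repetitions, with
    percentile-bootstrap confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    MASS,
    e1071,
    randomForest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
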