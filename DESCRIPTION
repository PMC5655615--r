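Package: ChanceQSAR
Title: Randomization Tests and Chance-Correlation Audits for QSAR Models
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating the predictive power of pure chance in
    QSAR (quantitative structure-activity relationship) modelling.
    Generates randomized copies of descriptor/activity tables by
    y-scrambling (response permutation), x-scrambling (per-descriptor
    permutation) and pseudo-descriptor sampling from fitted distributions,
    reproducibly from a master seed, over CSV and MDL SD (V2000) files
    with byte-preserving round trips.  Provides the model-fitting
    stand-ins needed for a chance audit (descriptor-pool reduction,
    ordinary least squares, exhaustive and genetic subset search over
    linear models, depth-limited classification trees), the regression
    validation statistics (r-squared, leave-one-out and leave-m-out
    q-squared, regression through the origin, Golbraikh-Tropsha criteria,
    cRp-squared, rm-squared, randomization intercepts) and the
    confusion-matrix classification metrics, and a harness that fits
    models on every randomized set and summarizes mean-highest scores
    with standard-deviation thresholds.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), rpart, withr, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
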