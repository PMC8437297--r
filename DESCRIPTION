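Package: mtgwas
Title: Multitrait Genome-Wide Association Analysis from Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint analysis of multiple genome-wide association studies from
    per-trait summary statistics alone. Provides harmonization and preprocessing
    of per-trait Z-scores (sample-size inference, low-sample-size filtering),
    robust estimation of the null Z-score covariance induced by sample overlap
    (naive, trimmed and cross-trait LD-score regression estimators), omnibus
    and weighted-sum multitrait association tests with pseudo-inverse handling
    of rank-deficient covariances, conditional-mean imputation of missing
    Z-scores from local linkage disequilibrium, LD-block locus discovery with
    greedy clumping, Gaussian-mixture clustering of multitrait association
    profiles under missing data, per-cluster genetic-correlation estimation
    with overlap-bias correction, and a simulation engine generating summary
    statistics with the statistical structure the methods assume.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    cluster,
    jsonlite
Suggests:
    Matrix,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
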