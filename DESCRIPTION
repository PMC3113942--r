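Package: pcdagg
Title: Aggregated Principal Component Discriminant Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Principal component discriminant analysis (PCDA) for
    high-dimensional omics matrices in which features far outnumber
    samples: Fisher linear discriminant analysis performed in a PCA score
    space where the within-class scatter matrix is invertible. The number
    of retained principal components is selected by a nested (double)
    cross-validation scheme, and the stochastic dependence of the
    cross-validation error on the random partition is addressed by
    repeating the scheme over many random splits and aggregating the
    resulting classifiers by majority voting. Per-sample voting margins
    diagnose unstable samples, stability curves trace the aggregated
    error as a function of the number of aggregated replicates, and
    rank products over the pooled discriminant vectors rank features by
    discriminative power. A two-class multivariate-normal simulator with
    a common (possibly singular) covariance parameterized from a
    reference data set supports classifier-stability experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, optparse
Suggests: testthat (>= 3.0.0), MASS, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils-internal.R'
    'io.R'
    'preprocess.R'
    'pcda.R'
    'doublecv.R'
    'ensemble.R'
    'rankproducts.R'
    'simulate.R'
    'report.R'
    'cli.R'
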