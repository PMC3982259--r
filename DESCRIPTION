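Package: fsvmcip
Title: Fuzzy Support Vector Machines for Imbalanced Classification with
    Locality-Preserving Regularization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements FSVM-CIP, a fuzzy support vector machine for
    imbalanced, noisy binary classification in linear and kernelized form.
    Per-sample fuzzy memberships down-weight likely outliers, class-specific
    cost scaling and a learned secondary margin offset counteract hyperplane
    skew towards the minority class, and a local within-class preserving
    scatter matrix regularizes the margin towards the intrinsic class
    geometry. Includes the associated evaluation protocol (stratified
    cross-validation, grid search, repeat-averaged sensitivity, specificity
    and accuracy reporting) and a synthetic-data generator for imbalanced
    Gaussian and curved-manifold two-class problems.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, kernlab
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
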