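Package: gpcmvpa
Title: Gaussian Process Classification of Multivoxel fMRI Activation Patterns
Version: 0.1.0
Authors@R: person("gpcmvpa", "developers", role = c("aut", "cre"),
    email = "gpcmvpa@example.org")
Description: A two-level pattern-recognition pipeline for event-related fMRI.
    At the first level, whole-brain condition coefficient (beta) patterns are
    decoded within each subject group by a binary Gaussian process classifier
    (linear kernel, probit likelihood, Laplace approximation), evaluated by
    leave-one-subject-out cross-validation with balanced accuracy and
    permutation testing, optionally after removing covariate-explained
    variance with a residual-forming matrix.  At the second level, the
    cross-validated predictive probabilities are compared across groups with a
    one-way ANOVA and Newman-Keuls post-hoc tests.  Includes an event-related
    paradigm simulator (canonical double-gamma HRF, Poisson-spaced stimuli),
    a first-level GLM, discriminating weight-map back-projection with
    fractional thresholding, and minimal NIfTI-1 input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
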