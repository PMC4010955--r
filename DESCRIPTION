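Package: permglm
Title: Permutation Inference for the General Linear Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Permutation and sign-flipping inference for contrasts of general
    linear model parameters in the presence of nuisance regressors. Implements
    the classical nuisance-handling strategies (Draper-Stoneman, Still-White,
    Freedman-Lane, Manly, ter Braak, Kennedy, Huh-Jhun, Smith, and a
    parametric reference), exchangeability blocks with within-block and
    whole-block shuffling, a heteroscedasticity-robust generalised statistic
    with variance groups (a Welch-type statistic that reduces to F and t in
    the homoscedastic case), exhaustive enumeration of unique shufflings or
    conditional Monte Carlo sampling, and multiple-testing correction across
    simultaneous tests by the distribution of the maximum statistic (FWER) or
    by the false discovery rate. A simulation module generates group and
    regression scenarios with controllable heteroscedasticity, regressor
    correlation and error laws, and runs calibration (type I error) and power
    studies with Wilson confidence intervals and Kolmogorov-Smirnov
    distribution comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    RNifti
Config/testthat/edition: 3
RoxygenNote: 7.3.3
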