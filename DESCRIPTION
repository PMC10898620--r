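Package: crteffects
Title: Defining and Estimating Causal Effects in Cluster Randomized Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for defining and estimating cluster-level and
    individual-level causal effects in two-arm cluster randomized trials.
    Implements the unadjusted contrast, the geometric-mean log-t-test, the
    covariate-adjusted residuals estimator (CARE), log-link generalized
    estimating equations with Fay-Graubard small-sample variance correction,
    augmented GEE, and three targeted maximum likelihood estimators
    (cluster-level, hierarchical, and hybrid TMLE) with influence-function
    based inference. Adaptive Prespecification selects among prespecified
    candidate adjustment regressions by cross-validated influence-function
    variance to maximize empirical efficiency while preserving Type-I error.
    Includes data-generating processes for two benchmark simulation studies
    (one with informative cluster size) and a replication harness computing
    power, coverage, and Type-I error over simulated trials.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports: graphics, stats, utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
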