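Package: multijm
Title: Multivariate Joint Models for Longitudinal and Time-to-Event Data via Monte Carlo EM
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Fits joint models linking multiple continuous longitudinal
    outcomes to a right-censored event time through a shared multivariate
    Gaussian random-effects process. The longitudinal sub-model is a
    multivariate linear mixed model; the event sub-model is a semiparametric
    proportional hazards model whose linear predictor includes a weighted sum
    of the subject-level random-effect trajectories. Estimation is by a Monte
    Carlo Expectation-Maximisation (MCEM) algorithm with antithetic variance
    reduction, dynamic Monte Carlo sample size, a nonparametric Breslow
    baseline hazard, and one-step Newton-Raphson or Gauss-Newton updates for
    the hazard coefficients. Standard errors come from the empirical profile
    information matrix or from a subject-level bootstrap. A joint-data
    simulator with Gompertz event times supports simulation studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    survival,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
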