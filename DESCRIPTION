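Package: recruitcast
Title: Recruitment Trajectory Analysis and Bayesian Accrual Prediction for Randomized Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for monitoring and predicting patient recruitment in
    multicenter randomized controlled trials. Builds recruitment
    trajectories from patient-level randomization dates, classifies trial
    completion, and predicts recruitment completion time and accrual with
    a conjugate Bayesian model (exponential waiting times with an
    inverse-gamma prior on the mean waiting time) alongside a
    constant-rate frequentist comparator. Includes a multicenter
    recruitment simulator (per-site Poisson processes with staggered site
    activation, cross-site rate heterogeneity and optional seasonality),
    descriptive recruitment-pattern analyses, and a landmark validation
    engine reporting percent relative bias, predictive-interval coverage
    and the posterior probability of late completion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
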