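Package: trustguilt
Title: Guilt Aversion and Inequity Aversion in Binary Trust Games
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Design, simulation and two-level estimation for a binary trust
    game in which the second mover trades off monetary reward, belief-dependent
    guilt and inequity. Provides seeded generation of 45-trial task designs
    with near-orthogonal Reward/Guilt/Inequity regressors, structural utility
    models (belief-dependent guilt, Fehr-Schmidt and absolute-difference
    inequity aversion) with logistic stochastic choice, synthetic two-country
    cohorts with Big Five and socioeconomic covariates, per-participant
    bias-reduced (Firth) logistic regression with BIC model comparison, and
    group-level inference: random-intercept mixed logistic regression fitted
    by Gauss-Hermite quadrature, L1-penalized (Lasso) regression of guilt
    sensitivity on gender, traits and their interactions with ten-fold
    cross-validation, and an ordinary-least-squares cross-check.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
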