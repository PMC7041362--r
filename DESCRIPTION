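Package: lfire
Title: Likelihood-Free Inference by Ratio Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Posterior inference for simulator-based models whose likelihood
    cannot be evaluated. The likelihood-to-marginal-likelihood ratio at each
    candidate parameter value is estimated by l1-penalised logistic regression
    discriminating summaries simulated at that value from summaries simulated
    under the prior predictive; exponentiating the fitted log-ratio at the
    observed summaries and multiplying by the prior yields an approximate
    posterior over a parameter grid. The penalty performs automatic summary
    statistic selection. Includes a coordinate-descent lasso logistic solver
    with warm-started regularisation paths and cross-validated penalty choice,
    and a built-in ARCH(1) time-series demonstration model.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    patchwork,
    generics,
    jsonlite,
    yaml,
    parallel
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
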