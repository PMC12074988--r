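Package: socialbasis
Title: Basis-Function Analysis of Multi-Agent Social Decisions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying group decision making with sequential
    basis functions. Implements the orthogonal weight-vector algebra that
    compresses four sequentially observed performance scores into a
    three-dimensional decision space, relevance sorting into primary,
    secondary and tertiary basis functions, and their inversion to an
    agent-centric frame. Includes generators for counterbalanced,
    decorrelated experimental schedules, logistic choice simulation under
    balanced and overweighting regimes, ridge-regularised logistic
    decision-weight estimation with a shared cross-validated penalty, a
    time-varying drift-diffusion model with attribute onset asynchrony
    fitted by differential evolution, and fMRI design-matrix and
    ROI time-course machinery validated on synthetic BOLD.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
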