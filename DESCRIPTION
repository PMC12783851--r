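Package: foragekernel
Title: Kernel-Based Modelling of Spatial Foraging Under Ambiguity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing spatial foraging decisions on
    a discrete grid of hidden food sources. Implements a generative choice
    model in which the probability of searching each site is a weighted sum
    of Gaussian kernel density fields encoding ambiguity (information yet to
    be gained), discovered reward, and proximity to the forager; agents
    sampling from this model, together with marginal and baseline
    strategies; path statistics including Levy-type step-size analysis,
    Hartigan's dip test of unimodality, outcome-conditioned step contrasts,
    and a convolutedness (roaming versus dwelling) index; and maximum
    likelihood estimation of the model weights and kernel sizes from
    recorded search sequences, with sigma grid search, subset bootstrap,
    and ROC-based comparison of fitted weight distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
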