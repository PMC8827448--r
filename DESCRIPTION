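Package: copulagp
Title: Conditional Copula Mixtures with Gaussian-Process Parameters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the dependence structure of continuous multivariate
    observations (for example simultaneously recorded neuronal and behavioral
    variables) as parametric bivariate copula mixtures whose parameters and
    mixing weights are latent Gaussian-process functions of a continuous
    covariate such as time or position.  Bivariate models are assembled into
    conditional canonical vines, model structure is chosen by the
    Watanabe-Akaike information criterion, and conditional entropy and mutual
    information are estimated by Monte-Carlo integration with posterior
    uncertainty.  Includes generators for synthetic benchmark data (a
    generalized-linear-model spiking simulator with calcium-kernel
    convolution, and Gaussian, Student-t and morphed-Gaussian benchmark
    distributions with analytic ground truth).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    readr,
    generics
Suggests:
    testthat (>= 3.0.0),
    tidyr,
    pracma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
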