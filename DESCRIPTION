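Package: joamodels
Title: Signal-Detection Models of Judgments of Agency and Confidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generative rating models for explicit judgments of agency (JoA)
    and decision confidence over delayed visual feedback of one's own
    movements. Implements a Second-order model in which ratings track the
    posterior probability that an agency decision is correct (and therefore
    require an internal estimate of sensory noise) and a First-order model in
    which ratings are a rescaled linear readout of the perceived delay signal.
    Provides the ordinal likelihood of 6-point ratings under both models, a
    12-bin variant for two-interval forced-choice (2IFC) confidence ratings,
    maximum-likelihood fitting with multistart derivative-free search, BIC and
    Akaike-weight comparison, random-effects Bayesian model selection with
    protected exceedance probabilities, seeded synthetic-session generators
    (including a 2-down-1-up adaptive staircase for the 2IFC task), and
    model- and parameter-recovery harnesses.
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
    lhs,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
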