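Package: popfpt
Title: Stochastic Population Models and First-Passage-Time Prediction of
    Extinction
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits discrete-time stochastic single-species population models
    with demographic and environmental variance to abundance time series by
    maximum likelihood on moment-matched one-step transition distributions
    (gamma, log-normal, negative binomial), optionally with AR/MA/ARMA
    structure on the growth-process errors as a single-species proxy for
    interspecific interactions.  Model adequacy for extinction prediction is
    assessed with simulated first-passage-time distributions, a
    first-passage-time likelihood and AIC, and the root mean square error of
    predicted passage times.  Includes the two-species to ARMA(2,1)
    reduction that motivates the autocorrelation structures, binomial
    observation-error and mean-time-to-extinction simulation studies, and
    generators for synthetic microcosm-like data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    lhs,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
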