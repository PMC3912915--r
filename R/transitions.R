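## Moment-matched one-step transition distributions.  Each family is
## parameterised so that its first two moments equal the conditional mean and
## variance of the population model exactly.

#' Match a gamma distribution to a mean and variance
#'
#' @param mu mean, positive.
#' @param V variance, positive.
#' @return list with `shape = mu^2/V` and `scale = V/mu`.
#' @examples
#' match_gamma(4, 8)  # shape 2, scale 2
#' @export
match_gamma <- function(mu, V) {
  .check_moments(mu, V)
  list(shape = mu^2 / V, scale = V / mu)
}

#' Match a log-normal distribution to a mean and variance
#'
#' @inheritParams match_gamma
#' @return list with `meanlog` and `sdlog`; `sdlog^2 = log(1 + V/mu^2)` and
#'   `meanlog = log(mu) - sdlog^2/2`.
#' @export
match_lognormal <- function(mu, V) {
  .check_moments(mu, V)
  s2 <- log1p(V / mu^2)
  list(meanlog = log(mu) - s2 / 2, sdlog = sqrt(s2))
}

#' Match a negative binomial distribution to a mean and variance
#'
#' Requires overdispersion (`V > mu`); at or below the Poisson boundary the
#' moments are infeasible for this family and an error of class
#' `"popfpt_overdispersion_error"` is signalled, which the likelihood code
#' converts into a penalty.
#'
#' @inheritParams match_gamma
#' @return list with `size = mu^2/(V - mu)` and `prob = size/(size + mu)`.
#' @export
match_negbinom <- function(mu, V) {
  .check_moments(mu, V)
  if (any(V <= mu)) {
    stop(structure(
      class = c("popfpt_overdispersion_error", "error", "condition"),
      list(message = "negative binomial requires V > mu", call = sys.call(-1))))
  }
  size <- mu^2 / (V - mu)
  list(size = size, prob = size / (size + mu))
}

.check_moments <- function(mu, V) {
  if (any(!is.finite(mu)) || any(!is.finite(V)) || any(mu <= 0) || any(V <= 0))
    stop("moment matching requires mu > 0 and V > 0")
}

#' Log-density of the moment-matched one-step transition
#'
#' Continuous families evaluate their density at `n_t`; the negative
#' binomial evaluates its pmf at `round(n_t)` (abundance counts are
#' integers; continuous synthetic states are rounded onto the lattice).
#'
#' @param n_t observed next abundance(s), nonnegative.
#' @param mu conditional mean(s).
#' @param V conditional variance(s).
#' @param family `"gamma"`, `"lognormal"` or `"negative_binomial"`.
#' @return log-density values.
#' @seealso [transition_logcell()] for the extinction cell used for
#'   observations below one individual.
#' @export
transition_logpdf <- function(n_t, mu, V,
                              family = c("gamma", "lognormal",
                                         "negative_binomial")) {
  family <- match.arg(family)
  if (any(n_t < 0)) stop("abundance must be nonnegative")
  switch(family,
    gamma = {
      p <- match_gamma(mu, V)
      stats::dgamma(n_t, shape = p$shape, scale = p$scale, log = TRUE)
    },
    lognormal = {
      p <- match_lognormal(mu, V)
      stats::dlnorm(n_t, meanlog = p$meanlog, sdlog = p$sdlog, log = TRUE)
    },
    negative_binomial = {
      p <- match_negbinom(mu, V)
      stats::dnbinom(round(n_t), size = p$size, prob = p$prob, log = TRUE)
    })
}

#' Log-probability of the extinction cell
#'
#' Continuous-state transition densities put zero mass on an exact zero, yet
#' extinct populations are observed as counts below one individual.  Such
#' observations are scored with the probability mass below one,
#' `log P(N < 1)`, so extinction events remain likelihood-compatible.  For
#' the negative binomial this is the pmf at zero.
#'
#' @inheritParams transition_logpdf
#' @return log cell probabilities.
#' @export
transition_logcell <- function(mu, V,
                               family = c("gamma", "lognormal",
                                          "negative_binomial")) {
  family <- match.arg(family)
  switch(family,
    gamma = {
      p <- match_gamma(mu, V)
      stats::pgamma(1, shape = p$shape, scale = p$scale, log.p = TRUE)
    },
    lognormal = {
      p <- match_lognormal(mu, V)
      stats::plnorm(1, meanlog = p$meanlog, sdlog = p$sdlog, log.p = TRUE)
    },
    negative_binomial = {
      p <- match_negbinom(mu, V)
      stats::dnbinom(0, size = p$size, prob = p$prob, log = TRUE)
    })
}

## Random one-step draws from the matched family.  V <= 0 collapses to the
## deterministic mean; an infeasible negative binomial (V <= mu) falls back
## to its Poisson limit, the closest member of the family.
.transition_sample <- function(mu, V, family) {
  out <- mu
  ok <- V > 0 & mu > 0
  if (!any(ok)) return(out)
  m <- mu[ok]; v <- V[ok]
  out[ok] <- switch(family,
    gamma = stats::rgamma(length(m), shape = m^2 / v, scale = v / m),
    lognormal = {
      s2 <- log1p(v / m^2)
      stats::rlnorm(length(m), meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
    },
    negative_binomial = {
      x <- numeric(length(m))
      od <- v > m
      if (any(od)) {
        size <- m[od]^2 / (v[od] - m[od])
        x[od] <- stats::rnbinom(sum(od), size = size, mu = m[od])
      }
      if (any(!od)) x[!od] <- stats::rpois(sum(!od), m[!od])
      x
    })
  out
}
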