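## AR/MA/ARMA structure on the growth-process errors, and the two-species
## linear system whose single-species margin is an ARMA(2,1) process --- the
## mechanistic reading of those error structures.

#' Recursive innovation filter on the log scale
#'
#' Given log-abundances `x_t` and the log-scale one-step expectations `m_t`
#' of the base model, computes the autocorrelation-adjusted expectations
#' `a_t = m_t + rho * e_[t-1] + theta * w_[t-1]`, the raw deviations
#' `e_t = x_t - m_t`, and the innovations `w_t = x_t - a_t`, starting from
#' `e_0 = w_0 = 0`.  With `rho = theta = 0` the filter is the identity:
#' `a_t = m_t` and `w_t = e_t`.
#'
#' The AR term acts on the raw deviation (a lagged-density-dependence
#' reading) and the MA term on the innovation; combined with the
#' density-dependent mean this yields an ARMA(2,1)-type dependence for the
#' log-abundances.
#'
#' @param x numeric vector of log-abundances (length at least 2).
#' @param m numeric vector of log-scale expectations, same length as `x`.
#' @param rho AR coefficient, `|rho| < 1`.
#' @param theta MA coefficient, `|theta| < 1`.
#' @return list with components `adjusted` (`a_t`), `deviations` (`e_t`)
#'   and `innovations` (`w_t`).
#' @export
innovation_filter <- function(x, m, rho = 0, theta = 0) {
  if (length(x) != length(m)) stop("x and m must have equal length")
  if (length(x) < 2) stop("need a series of length at least 2")
  if (abs(rho) >= 1 || abs(theta) >= 1) stop("|rho| and |theta| must be < 1")
  T <- length(x)
  a <- e <- w <- numeric(T)
  e_prev <- 0; w_prev <- 0
  for (t in seq_len(T)) {
    a[t] <- m[t] + rho * e_prev + theta * w_prev
    e[t] <- x[t] - m[t]
    w[t] <- x[t] - a[t]
    e_prev <- e[t]; w_prev <- w[t]
  }
  list(adjusted = a, deviations = e, innovations = w)
}

#' Autocorrelation-adjusted transition moments
#'
#' Multiplies the base conditional mean by `exp(rho * e_prev + theta *
#' w_prev)` and recomputes the variance from the adjusted mean, so the
#' correlation structure affects both the demographic and the environmental
#' variance components.
#'
#' @param n_prev previous abundance(s).
#' @param e_prev lagged raw deviation(s) from [innovation_filter()].
#' @param w_prev lagged innovation(s).
#' @param model a [pop_model()].
#' @return list with `mu` and `V`, the adjusted mean and variance.
#' @export
adjusted_moments <- function(n_prev, e_prev, w_prev, model) {
  mu0 <- conditional_mean(n_prev, model)
  mu <- mu0 * exp(model$params$rho * e_prev + model$params$theta * w_prev)
  list(mu = mu, V = .cond_var_at_mu(n_prev, mu, model))
}

#' Two interacting species on the log scale
#'
#' Linear (vector-autoregressive) dynamics
#' `X(t) = B X(t-1) + W(t)` for the log-abundance deviations of a focal
#' species (`X1`) and an interacting species (`X2`).  `b11` and `b22` are
#' intraspecific density-dependence terms, `b12` and `b21` interspecific
#' interaction terms, and the `W` are independent Gaussian noises
#' representing demographic and environmental stochasticity.
#'
#' Stationarity requires the roots of
#' `1 - (b11 + b22) z + (b11 b22 - b12 b21) z^2` to lie outside the unit
#' circle; the boundary case `b22 = 1` (the interacting species performs a
#' random walk) is explicitly admitted because it maximises the induced MA
#' effect.
#'
#' @param b11,b12,b21,b22 interaction coefficients.
#' @param w1_sd,w2_sd noise standard deviations, nonnegative.
#' @return object of class `"two_species_system"`.
#' @export
two_species_system <- function(b11, b12, b21, b22, w1_sd = 1, w2_sd = 1) {
  if (w1_sd < 0 || w2_sd < 0) stop("noise standard deviations must be >= 0")
  B <- matrix(c(b11, b21, b12, b22), 2, 2)  # column-major: [b11 b12; b21 b22]
  lam <- max(Mod(eigen(B, only.values = TRUE)$values))
  if (lam >= 1 && b22 != 1)
    stop("system is non-stationary (spectral radius ", signif(lam, 3),
         "); only the random-walk case b22 = 1 is admitted")
  structure(list(b11 = b11, b12 = b12, b21 = b21, b22 = b22,
                 w1_sd = w1_sd, w2_sd = w2_sd, B = B),
            class = "two_species_system")
}

#' Reduce the two-species system to the focal species' ARMA(2,1)
#'
#' Marginalising the interacting species gives
#' `(1 - phi1 L - phi2 L^2) X1_t = U_t` with AR coefficients
#' `phi1 = b11 + b22` and `phi2 = b12 b21 - b11 b22` (the AR(2) magnitude
#' is the difference between inter- and intraspecific interactions), and
#' composite noise `U_t = W1_t - b22 W1_[t-1] + b12 W2_[t-1]`.  `U` is an
#' MA(1) process; its coefficient `theta1` and innovation standard
#' deviation are obtained by matching the lag-0 and lag-1 autocovariances,
#' taking the invertible root.
#'
#' @param sys a [two_species_system()].
#' @return list with `phi1`, `phi2`, `theta1`, `innovation_sd`.
#' @examples
#' var_to_arma(two_species_system(0.5, 0, 0, 0.8))  # theta1 = -0.8
#' @export
var_to_arma <- function(sys) {
  stopifnot(inherits(sys, "two_species_system"))
  phi1 <- sys$b11 + sys$b22
  phi2 <- sys$b12 * sys$b21 - sys$b11 * sys$b22
  g0 <- sys$w1_sd^2 * (1 + sys$b22^2) + sys$b12^2 * sys$w2_sd^2
  g1 <- -sys$b22 * sys$w1_sd^2
  if (g0 <= 0) stop("composite noise has zero variance")
  c1 <- g1 / g0
  if (abs(c1) < .Machine$double.eps) {
    theta1 <- 0
    s2 <- g0
  } else {
    # theta/(1+theta^2) = c1; invertible root |theta| < 1
    theta1 <- (1 - sqrt(1 - 4 * c1^2)) / (2 * c1)
    s2 <- g1 / theta1
  }
  list(phi1 = phi1, phi2 = phi2, theta1 = theta1, innovation_sd = sqrt(s2))
}

#' Hannan-Rissanen estimate of an ARMA(2,1) model
#'
#' Two-stage least-squares estimator: a long autoregression (Yule-Walker,
#' order 30) supplies approximate innovations, then the series is regressed
#' on its first two lags and the lagged innovation.  Non-iterative, so it
#' cannot diverge, and consistent with near-maximum-likelihood efficiency
#' at the long series lengths used in the reduction-equivalence checks.
#'
#' @param x numeric series (zero-mean).
#' @return named vector `phi1`, `phi2`, `theta1`.
#' @export
estimate_arma21 <- function(x) {
  p <- 30L
  a <- stats::ar(x, order.max = p, aic = FALSE, method = "yule-walker")
  e <- stats::filter(x, c(1, -a$ar), sides = 1)
  idx <- (p + 2L):length(x)
  X <- cbind(x[idx - 1], x[idx - 2], e[idx - 1])
  co <- qr.solve(X, x[idx])
  c(phi1 = co[1], phi2 = co[2], theta1 = co[3])
}

#' Asymptotic standard errors of ARMA(2,1) coefficient estimates
#'
#' Whittle (frequency-domain) Fisher information for a Gaussian ARMA(2,1)
#' process, inverted and scaled by the series length.  Returns `Inf` when
#' the information matrix is singular, which happens exactly when the AR
#' and MA polynomials share a root (the model is then unidentifiable).
#'
#' @param phi1,phi2 AR coefficients.
#' @param theta1 MA coefficient.
#' @param n series length.
#' @return named vector of standard errors for `phi1`, `phi2`, `theta1`.
#' @export
arma21_asymptotic_se <- function(phi1, phi2, theta1, n) {
  K <- 512L
  om <- pi * (seq_len(K) - 0.5) / K
  z <- exp(-1i * om)
  G <- cbind(2 * Re(z / (1 - phi1 * z - phi2 * z^2)),
             2 * Re(z^2 / (1 - phi1 * z - phi2 * z^2)),
             2 * Re(z / (1 + theta1 * z)))
  I <- crossprod(G) / (2 * K)
  V <- tryCatch(solve(I), error = function(e) NULL)
  if (is.null(V)) return(stats::setNames(rep(Inf, 3),
                                         c("phi1", "phi2", "theta1")))
  stats::setNames(sqrt(pmax(diag(V), 0) / n), c("phi1", "phi2", "theta1"))
}

#' Draw a random stationary, identifiable two-species system
#'
#' Rejection sampler over intraspecific coefficients `b11, b22 ~ U(0.3,
#' 0.8)` and interspecific coefficients with magnitude `U(0.15, 0.5)` and
#' random signs, accepting systems whose spectral radius lies in
#' `[0.55, 0.85]` (persistent but comfortably stationary dynamics) and
#' whose induced ARMA(2,1) coefficients are statistically identifiable: the
#' asymptotic standard errors of `phi1` and `phi2` at series length
#' `n_check` must not exceed `se_max`.  The screen excludes near AR/MA
#' root cancellations, for which no estimator can recover the coefficients.
#'
#' @param n_check series length used in the identifiability screen.
#' @param se_max largest admissible asymptotic standard error.
#' @return a [two_species_system()] (with the [var_to_arma()] reduction
#'   attached as attribute `"reduction"`).
#' @export
random_stationary_system <- function(n_check = 1e5, se_max = 0.008) {
  repeat {
    b11 <- stats::runif(1, 0.3, 0.8)
    b22 <- stats::runif(1, 0.3, 0.8)
    b12 <- sample(c(-1, 1), 1) * stats::runif(1, 0.15, 0.5)
    b21 <- sample(c(-1, 1), 1) * stats::runif(1, 0.15, 0.5)
    B <- matrix(c(b11, b21, b12, b22), 2, 2)
    sr <- max(Mod(eigen(B, only.values = TRUE)$values))
    if (sr < 0.55 || sr > 0.85) next
    sys <- tryCatch(two_species_system(b11, b12, b21, b22, 1, 1),
                    error = function(e) NULL)
    if (is.null(sys)) next
    red <- var_to_arma(sys)
    se <- arma21_asymptotic_se(red$phi1, red$phi2, red$theta1, n_check)
    if (max(se[c("phi1", "phi2")]) > se_max) next
    attr(sys, "reduction") <- red
    return(sys)
  }
}

#' Simulate the two-species system
#'
#' @param sys a [two_species_system()].
#' @param steps number of retained time steps (at least 2).
#' @param burn_in steps discarded before recording.
#' @param init initial state (log-abundance deviations).
#' @param seed optional integer seed.
#' @return `steps x 2` matrix of log-abundance deviations (`x1`, `x2`).
#' @export
simulate_two_species <- function(sys, steps, burn_in = 100, init = c(0, 0),
                                 seed = NULL) {
  stopifnot(inherits(sys, "two_species_system"), steps >= 2)
  if (!is.null(seed)) set.seed(seed)
  total <- burn_in + steps
  w1 <- stats::rnorm(total, 0, sys$w1_sd)
  w2 <- stats::rnorm(total, 0, sys$w2_sd)
  x <- matrix(0, total, 2)
  prev <- init
  for (t in seq_len(total)) {
    prev <- c(sys$b11 * prev[1] + sys$b12 * prev[2] + w1[t],
              sys$b21 * prev[1] + sys$b22 * prev[2] + w2[t])
    x[t, ] <- prev
  }
  out <- x[(burn_in + 1):total, , drop = FALSE]
  colnames(out) <- c("x1", "x2")
  out
}
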