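## One-step transition likelihood, multi-start maximum-likelihood fitting,
## and information criteria on abundances.

## negative log-likelihood contribution of a single series
.nll_series <- function(counts, model) {
  n <- counts
  low <- which(n < 1)
  if (length(low)) n <- n[seq_len(low[1])]
  m <- length(n)
  if (m < 2) return(0)
  n_prev <- n[-m]
  n_next <- n[-1]
  mu <- conditional_mean(n_prev, model)
  if (any(!is.finite(mu)) || any(mu <= 0)) return(Inf)
  if (model$autocorrelation == "none") {
    mu_star <- mu
  } else {
    rho <- model$params$rho; theta <- model$params$theta
    logmu <- log(mu)
    mu_star <- numeric(m - 1)
    e_prev <- 0; w_prev <- 0
    for (i in seq_len(m - 1)) {
      a <- logmu[i] + rho * e_prev + theta * w_prev
      mu_star[i] <- exp(a)
      if (n_next[i] >= 1) {
        x <- log(n_next[i])
        e_prev <- x - logmu[i]
        w_prev <- x - a
      }
    }
  }
  V <- .cond_var_at_mu(n_prev, mu_star, model)
  if (any(!is.finite(mu_star)) || any(mu_star <= 0) ||
      any(!is.finite(V)) || any(V <= 0)) return(Inf)
  if (model$transition == "negative_binomial" && any(V <= mu_star))
    return(Inf)
  absorbed <- n_next < 1
  ll <- numeric(m - 1)
  if (any(!absorbed))
    ll[!absorbed] <- transition_logpdf(n_next[!absorbed], mu_star[!absorbed],
                                       V[!absorbed], model$transition)
  if (any(absorbed))
    ll[absorbed] <- transition_logcell(mu_star[absorbed], V[absorbed],
                                       model$transition)
  if (any(!is.finite(ll))) return(Inf)
  -sum(ll)
}

.n_transitions <- function(series) {
  sum(vapply(.as_series_list(series), function(s)
    max(length(.retained_counts(s)) - 1L, 0L), 0L))
}

#' Negative log-likelihood of abundance series under a model
#'
#' The joint probability of the observations is the product of the one-step
#' transition densities, with moments adjusted by the model's AR/MA filter;
#' replicates share one parameter set and contribute additively.
#' Observations below one individual are scored with the extinction cell
#' (see [transition_logcell()]) and terminate their series.  Infeasible
#' moments (for example negative binomial without overdispersion) yield
#' `Inf`, which the optimiser treats as a penalty.
#'
#' @param series an [abundance_series()] or list of them.
#' @param model a [pop_model()].
#' @param params optional named parameter values overriding the model's.
#' @return scalar negative log-likelihood.
#' @export
neg_log_likelihood <- function(series, model, params = NULL) {
  if (!is.null(params)) model <- set_params(model, params)
  sum(vapply(.as_series_list(series),
             function(s) .nll_series(s$counts, model), 0))
}

## ---- parameter transforms -------------------------------------------------
## positive parameters are fitted on the log scale; AR/MA coefficients on an
## atanh scale bounded at +/- 0.99

.to_working <- function(p, names) {
  vapply(names, function(nm) {
    if (nm %in% c("rho", "theta")) atanh(p[[nm]] / 0.99) else log(p[[nm]])
  }, 0)
}

.from_working <- function(z, names) {
  out <- lapply(seq_along(names), function(i) {
    if (names[i] %in% c("rho", "theta")) 0.99 * tanh(z[i]) else exp(z[i])
  })
  names(out) <- names
  out
}

## natural-scale box constraints; b is additionally bounded for the logistic
## form so that survival stays in (0, 1] over the observed abundances
.param_bounds <- function(model, max_n) {
  b_hi <- if (model$density_dependence == "logistic") 1 / max_n else 10
  list(r = c(1e-6, 100), b = c(1e-9, b_hi),
       sigma_d2 = c(1e-8, 1e3), sigma_e2 = c(1e-8, 1e3),
       rho = c(-0.99, 0.99), theta = c(-0.99, 0.99))
}

## crude data-driven starting values from a log-growth regression
.start_guess <- function(series, model) {
  lr <- c(); pred <- c(); nprev <- c()
  for (s in .as_series_list(series)) {
    n <- .retained_counts(s)
    if (length(n) < 2) next
    np <- n[-length(n)]; nn <- n[-1]
    keep <- np >= 1 & nn >= 1
    lr <- c(lr, log(nn[keep] / np[keep]))
    nprev <- c(nprev, np[keep])
  }
  if (length(lr) < 3) return(NULL)
  x <- switch(model$density_dependence,
    gompertz = log(pmax(nprev, 1)),
    exponential = NULL,
    nprev)
  if (is.null(x)) {
    r0 <- exp(mean(lr)); b0 <- 1e-9
    s2 <- stats::var(lr)
  } else {
    fit <- stats::lm(lr ~ x)
    r0 <- exp(stats::coef(fit)[1])
    b0 <- max(-stats::coef(fit)[2], 1e-6)
    s2 <- mean(stats::resid(fit)^2)
  }
  s2 <- max(s2, 1e-4)
  g <- list(r = min(max(r0, 0.05), 50), b = b0,
            sigma_d2 = s2 / 2 * mean(nprev), sigma_e2 = s2 / 2,
            rho = 0, theta = 0)
  bounds <- .param_bounds(model, max(nprev))
  for (nm in names(g)) g[[nm]] <- min(max(g[[nm]], bounds[[nm]][1] * 1.01),
                                      bounds[[nm]][2] * 0.99)
  g
}

## penalised working-scale objective shared by fit_mle and profile_ci
.make_objective <- function(series, model, free, bounds) {
  function(z) {
    p <- .from_working(z, free)
    for (nm in free) {
      bb <- bounds[[nm]]
      if (p[[nm]] < bb[1] || p[[nm]] > bb[2])
        return(1e10 + sum(z^2))
    }
    v <- neg_log_likelihood(series, model, p)
    if (!is.finite(v)) return(1e10) else v
  }
}

#' Fit a population model by maximum likelihood
#'
#' Multi-start bounded optimisation of the one-step transition likelihood.
#' Positive parameters are optimised on the log scale and AR/MA coefficients
#' on an atanh scale; starting points combine a data-driven growth-regression
#' guess with Latin-hypercube perturbations.  Standard errors come from the
#' numerical Hessian at the optimum (on the working scale).
#'
#' To fit each replicate separately, call `fit_mle` on single series;
#' passing a list pools the replicates under one shared parameter set.
#'
#' @param series an [abundance_series()] or list of them.
#' @param model a [pop_model()] defining the structure to fit.
#' @param starts number of optimiser starts.
#' @param seed optional integer seed (start placement is stochastic).
#' @param maxit iteration cap per Nelder-Mead start.
#' @return object of class `"pop_fit"` with elements `params`, `loglik`,
#'   `k`, `aic`, `bic`, `converged`, `se_working`, `model`,
#'   `n_transitions` and optimiser diagnostics.
#' @export
fit_mle <- function(series, model, starts = 20, seed = NULL, maxit = 500) {
  series <- .as_series_list(series)
  if (!is.null(seed)) set.seed(seed)
  free <- free_param_names(model)
  k <- length(free)
  ntr <- .n_transitions(series)
  if (ntr < k + 2) stop("insufficient data: ", ntr, " transitions for ",
                        k, " parameters")
  max_n <- max(vapply(series, function(s) max(s$counts), 0))
  bounds <- .param_bounds(model, max_n)

  obj <- .make_objective(series, model, free, bounds)

  guess <- .start_guess(series, model)
  if (is.null(guess)) guess <- list(r = 1, b = 1e-3, sigma_d2 = 1,
                                    sigma_e2 = 0.01, rho = 0, theta = 0)
  z0 <- .to_working(guess, free)
  zs <- matrix(rep(z0, each = starts), nrow = starts)
  if (starts > 1) {
    spread <- ifelse(free %in% c("rho", "theta"), 0.8, 1.5)
    u <- lhs::randomLHS(starts - 1, k)
    zs[-1, ] <- sweep((u - 0.5) * 2, 2, spread, `*`) +
      matrix(rep(z0, each = starts - 1), nrow = starts - 1)
  }

  best <- NULL
  n_fail <- 0
  for (i in seq_len(starts)) {
    o <- tryCatch(stats::optim(zs[i, ], obj, method = "Nelder-Mead",
                               control = list(maxit = maxit)),
                  error = function(e) NULL)
    if (is.null(o) || !is.finite(o$value) || o$value >= 1e10) {
      n_fail <- n_fail + 1
      next
    }
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best))
    stop("all optimiser starts failed (", n_fail, " of ", starts, ")")
  # polish: restart Nelder-Mead from the incumbent until the value
  # stabilises (a single run often stops at the iteration cap)
  converged <- best$convergence == 0
  for (rep in 1:3) {
    o2 <- tryCatch(stats::optim(best$par, obj, method = "Nelder-Mead",
                                control = list(maxit = 2 * maxit,
                                               reltol = 1e-10)),
                   error = function(e) NULL)
    if (is.null(o2) || !is.finite(o2$value) || o2$value > best$value) break
    impr <- best$value - o2$value
    best <- o2
    converged <- o2$convergence == 0
    if (impr < 1e-7 * (1 + abs(o2$value))) {
      converged <- TRUE
      break
    }
  }

  H <- tryCatch(stats::optimHess(best$par, obj), error = function(e) NULL)
  se <- rep(NA_real_, k)
  if (!is.null(H)) {
    Vz <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(Vz)) {
      d <- diag(Vz)
      se <- sqrt(pmax(d, 0))
      se[d <= 0] <- NA_real_
    }
  }
  names(se) <- free

  p_hat <- .from_working(best$par, free)
  loglik <- -best$value
  structure(list(
    params = unlist(p_hat),
    loglik = loglik,
    k = k,
    aic = -2 * loglik + 2 * k,
    bic = -2 * loglik + k * log(ntr),
    converged = converged,
    se_working = se,
    working = stats::setNames(best$par, free),
    n_transitions = ntr,
    n_failed_starts = n_fail,
    model = set_params(model, p_hat)),
    class = "pop_fit")
}

#' @export
print.pop_fit <- function(x, ...) {
  cat("Maximum-likelihood fit:", model_label(x$model), "\n")
  cat("  logLik", signif(x$loglik, 6), " k =", x$k,
      " AIC", signif(x$aic, 6), " BIC", signif(x$bic, 6),
      if (!x$converged) " [NOT CONVERGED]", "\n")
  print(signif(x$params, 4))
  invisible(x)
}

#' Parameter confidence intervals from the working-scale Hessian
#'
#' Intervals of plus/minus `z` standard errors on the working scale
#' (log for positive parameters, atanh for AR/MA coefficients), mapped back
#' to the natural scale.
#'
#' @param object a [fit_mle()] result.
#' @param parm parameters to include (default all).
#' @param level unused; intervals are `z`-standard-error intervals.
#' @param z half-width in standard errors (default 2).
#' @param ... ignored.
#' @return matrix with columns `lower`, `estimate`, `upper`.
#' @export
confint.pop_fit <- function(object, parm = NULL, level = NULL, z = 2, ...) {
  free <- names(object$working)
  if (is.null(parm)) parm <- free
  out <- t(vapply(parm, function(nm) {
    zc <- object$working[[nm]]; s <- object$se_working[[nm]]
    lo <- unlist(.from_working(zc - z * s, nm))
    hi <- unlist(.from_working(zc + z * s, nm))
    est <- unlist(.from_working(zc, nm))
    c(lower = min(lo, hi), estimate = est, upper = max(lo, hi))
  }, c(lower = 0, estimate = 0, upper = 0)))
  out
}

#' Profile-likelihood parameter intervals
#'
#' Interval endpoints are where the profile negative log-likelihood rises
#' `z^2/2` above its minimum (for `z = 2`, the deviance level equivalent to
#' a 2-standard-error Wald interval).  Unlike Hessian-based intervals these
#' remain meaningful when the likelihood surface is a ridge or the estimate
#' sits at a parameter bound, as happens when the demographic and
#' environmental variance scales are weakly separated.  The search expands
#' outward on the working scale and bisects the crossing; an endpoint that
#' never crosses before its box constraint is reported at the constraint.
#'
#' @param fit a [fit_mle()] result.
#' @param series the data the model was fitted to.
#' @param parm parameter names to profile (default: all free parameters).
#' @param z interval half-width in standard-error equivalents.
#' @param maxit iteration cap for each nuisance re-optimisation.
#' @return matrix with columns `lower`, `estimate`, `upper`.
#' @export
profile_ci <- function(fit, series, parm = NULL, z = 2, maxit = 200) {
  series <- .as_series_list(series)
  free <- names(fit$working)
  if (is.null(parm)) parm <- free
  model <- fit$model
  max_n <- max(vapply(series, function(s) max(s$counts), 0))
  bounds <- .param_bounds(model, max_n)
  target <- -fit$loglik + z^2 / 2

  prof_nll <- function(nm, zj, warm) {
    others <- setdiff(free, nm)
    assemble <- function(zo) {
      full <- numeric(length(free))
      names(full) <- free
      full[nm] <- zj
      full[others] <- zo
      full[free]
    }
    obj_full <- .make_objective(series, model, free, bounds)
    if (!length(others)) return(list(value = obj_full(assemble(NULL)),
                                     warm = NULL))
    o <- stats::optim(warm, function(zo) obj_full(assemble(zo)),
                      method = "Nelder-Mead",
                      control = list(maxit = maxit))
    list(value = o$value, warm = o$par)
  }

  zbound <- function(nm) {
    bb <- bounds[[nm]]
    if (nm %in% c("rho", "theta")) {
      lim <- atanh(pmin(pmax(bb / 0.99, -1 + 1e-6), 1 - 1e-6))
    } else lim <- log(bb)
    lim
  }

  one_side <- function(nm, dir) {
    zhat <- fit$working[[nm]]
    warm <- fit$working[setdiff(free, nm)]
    lim <- zbound(nm)[if (dir > 0) 2 else 1]
    step <- 0.25
    z_in <- zhat; f_in <- -fit$loglik
    repeat {
      z_out <- z_in + dir * step
      at_lim <- (dir > 0 && z_out >= lim) || (dir < 0 && z_out <= lim)
      if (at_lim) z_out <- lim
      p <- prof_nll(nm, z_out, warm)
      warm <- if (is.null(p$warm)) warm else p$warm
      if (p$value >= target) break
      z_in <- z_out; f_in <- p$value
      if (at_lim) return(unlist(.from_working(lim, nm)))
      step <- step * 2
    }
    # bisect the crossing between z_in and z_out
    f_out <- p$value
    for (it in 1:8) {
      zm <- (z_in + z_out) / 2
      p <- prof_nll(nm, zm, warm)
      warm <- if (is.null(p$warm)) warm else p$warm
      if (p$value >= target) { z_out <- zm; f_out <- p$value }
      else { z_in <- zm; f_in <- p$value }
    }
    unlist(.from_working((z_in + z_out) / 2, nm))
  }

  out <- t(vapply(parm, function(nm) {
    est <- unlist(.from_working(fit$working[[nm]], nm))
    lo <- one_side(nm, -1)
    hi <- one_side(nm, +1)
    c(lower = min(lo, hi), estimate = est, upper = max(lo, hi))
  }, c(lower = 0, estimate = 0, upper = 0)))
  out
}

#' Profile deviance at fixed parameter values
#'
#' Twice the gap between the profile negative log-likelihood with the named
#' parameters held fixed (all others re-optimised) and the fitted minimum.
#' Comparing the deviance with a chi-squared quantile on `length(fix)`
#' degrees of freedom gives joint confidence regions that remain valid on
#' likelihood ridges, where marginal intervals for the individual
#' parameters can be badly behaved.
#'
#' @param fit a [fit_mle()] result.
#' @param series the data the model was fitted to.
#' @param fix named numeric vector of parameter values to hold fixed.
#' @param maxit iteration cap for the nuisance re-optimisation.
#' @return the deviance (nonnegative up to optimiser slack).
#' @export
profile_deviance <- function(fit, series, fix, maxit = 800) {
  series <- .as_series_list(series)
  free <- names(fit$working)
  stopifnot(all(names(fix) %in% free))
  model <- fit$model
  max_n <- max(vapply(series, function(s) max(s$counts), 0))
  obj <- .make_objective(series, model, free,
                         .param_bounds(model, max_n))
  zfix <- .to_working(as.list(fix), names(fix))
  others <- setdiff(free, names(fix))
  if (!length(others)) {
    v <- obj(zfix[free])
  } else {
    o <- stats::optim(fit$working[others], function(zo) {
      z <- c(zo, zfix)[free]
      obj(z)
    }, method = "Nelder-Mead", control = list(maxit = maxit))
    v <- o$value
  }
  2 * (v + fit$loglik)
}

#' Information-criterion table for a set of fits
#'
#' @param fits list of [fit_mle()] results fitted to identical data.
#' @param labels optional model labels.
#' @return data frame with `model`, `k`, `loglik`, `aic`, `bic`,
#'   `delta_aic` (relative to the set minimum) and a `best` flag (ties
#'   broken by smaller `k`).
#' @export
information_criteria <- function(fits, labels = NULL) {
  if (is.null(labels))
    labels <- vapply(fits, function(f) model_label(f$model), "")
  df <- data.frame(
    model = labels,
    k = vapply(fits, `[[`, 0, "k"),
    loglik = vapply(fits, `[[`, 0, "loglik"),
    aic = vapply(fits, `[[`, 0, "aic"),
    bic = vapply(fits, `[[`, 0, "bic"))
  df$delta_aic <- df$aic - min(df$aic)
  tol <- 1e-8
  cand <- which(df$delta_aic <= tol)
  best <- cand[which.min(df$k[cand])]
  df$best <- seq_len(nrow(df)) == best
  df
}
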