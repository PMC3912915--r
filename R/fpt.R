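## First-passage-time machinery: forward simulation of the fitted transition
## model, empirical fpt distributions, the fpt likelihood/AIC, and RMSE.

## one vectorised simulation step across a batch of trajectories; extinction
## (state < 1) is absorbing with the state set to 0
.sim_advance <- function(state, e, w, model) {
  alive <- state >= 1
  ns <- numeric(length(state))
  if (any(alive)) {
    na <- state[alive]
    mu0 <- conditional_mean(na, model)
    withacf <- model$autocorrelation != "none"
    mu_s <- if (withacf)
      mu0 * exp(model$params$rho * e[alive] + model$params$theta * w[alive])
    else mu0
    V <- .cond_var_at_mu(na, mu_s, model)
    draw <- .transition_sample(mu_s, V, model$transition)
    pos <- draw >= 1
    if (withacf) {
      en <- wn <- numeric(length(draw))
      if (any(pos)) {
        lx <- log(draw[pos])
        en[pos] <- lx - log(mu0[pos])
        wn[pos] <- lx - log(mu_s[pos])
      }
      e[alive] <- en
      w[alive] <- wn
    }
    draw[!pos] <- 0
    ns[alive] <- draw
  }
  list(state = ns, e = e, w = w)
}

#' Simulate one abundance trajectory from a model
#'
#' Iteratively samples each next abundance from the moment-matched
#' transition family at the (autocorrelation-adjusted) conditional mean and
#' variance.  A state below one individual is treated as extinct: it is
#' recorded as 0 and the trajectory stays at 0 thereafter.  With both
#' variance scales zero the map is deterministic, `n_t = r n p(n)`.
#'
#' @param model a [pop_model()] carrying its parameters.
#' @param n0 initial abundance, positive.
#' @param horizon number of steps to simulate.
#' @param seed optional integer seed.
#' @return numeric vector of length `horizon + 1` starting at `n0`.
#' @export
simulate_trajectory <- function(model, n0, horizon, seed = NULL) {
  stopifnot(n0 > 0, horizon >= 1)
  if (!is.null(seed)) set.seed(seed)
  out <- numeric(horizon + 1)
  out[1] <- n0
  st <- list(state = n0, e = 0, w = 0)
  for (t in seq_len(horizon)) {
    st <- .sim_advance(st$state, st$e, st$w, model)
    out[t + 1] <- st$state
    if (st$state < 1) break
  }
  out
}

#' First passage time of a series below a threshold
#'
#' The smallest `t >= 0` (in sampling steps, counting the first observation
#' as `t = 0`) with `n_t <= threshold`; `NA` if the series never reaches the
#' threshold (censored).
#'
#' @param series numeric abundance vector or an [abundance_series()].
#' @param threshold positive quasi-extinction abundance.
#' @return integer step, or `NA_integer_` if censored.
#' @export
first_passage_time <- function(series, threshold) {
  if (inherits(series, "abundance_series")) series <- series$counts
  if (threshold <= 0) stop("threshold must be positive")
  idx <- which(series <= threshold)
  if (!length(idx)) return(NA_integer_)
  as.integer(idx[1] - 1L)
}

#' Observed first passage times at every observed abundance
#'
#' Thresholds are the unique observed abundances (at or above one
#' individual) of the retained series; the passage time to each is measured
#' in sampling steps from the first retained observation.  Every threshold
#' is crossed at its own observation time at the latest, so none are
#' censored.
#'
#' @param series an [abundance_series()].
#' @return data frame with `threshold` (decreasing) and `fpt` (steps).
#' @export
observed_fpts <- function(series) {
  n <- .retained_counts(series)
  if (!length(n)) stop("empty series")
  thr <- sort(unique(n[n >= 1]), decreasing = TRUE)
  fpt <- vapply(thr, function(th) first_passage_time(n, th), 0L)
  data.frame(threshold = thr, fpt = fpt)
}

## Empirical fpt counts for a set of thresholds from S simulated
## trajectories.  Returns an (n thresholds) x (horizon + 1) matrix of
## crossing counts; thresholds must be sorted decreasing.  Work is chunked
## so memory stays bounded, and trajectories stop being advanced once they
## have crossed every threshold.
.fpt_counts <- function(model, n0, thresholds, S, horizon, chunk = NULL) {
  thr <- thresholds
  if (is.unsorted(rev(thr))) thr <- sort(thr, decreasing = TRUE)
  nthr <- length(thr)
  counts <- matrix(0L, nthr, horizon + 1L)
  if (is.null(chunk)) chunk <- as.integer(max(1000L, min(S, 50000L)))
  done <- 0L
  while (done < S) {
    B <- as.integer(min(chunk, S - done))
    state <- rep(as.numeric(n0), B)
    e <- w <- numeric(B)
    ptr <- rep(1L, B)
    t <- 0L
    repeat {
      # record all thresholds crossed at this step
      repeat {
        hit <- which(ptr <= nthr & state <= thr[pmin(ptr, nthr)])
        if (!length(hit)) break
        counts[, t + 1L] <- counts[, t + 1L] + tabulate(ptr[hit], nbins = nthr)
        ptr[hit] <- ptr[hit] + 1L
      }
      active <- ptr <= nthr
      if (!any(active) || t >= horizon) break
      if (mean(active) < 0.5) {
        keep <- which(active)
        state <- state[keep]; e <- e[keep]; w <- w[keep]; ptr <- ptr[keep]
      }
      st <- .sim_advance(state, e, w, model)
      state <- st$state; e <- st$e; w <- st$w
      t <- t + 1L
    }
    done <- done + B
  }
  counts
}

#' Empirical first-passage-time distribution
#'
#' Simulates `S` trajectories from `n0` and tabulates the first passage
#' time below `threshold` over steps `0..horizon`; mass beyond the horizon
#' is reported separately as `censored`.
#'
#' @inheritParams simulate_trajectory
#' @param threshold positive quasi-extinction abundance.
#' @param S number of simulations.
#' @return list with `pmf` (named vector over steps `0..horizon`, summing
#'   with `censored` to 1) and `censored`.
#' @export
fpt_distribution <- function(model, n0, threshold, S, horizon, seed = NULL) {
  stopifnot(S >= 1, threshold > 0)
  if (!is.null(seed)) set.seed(seed)
  cm <- .fpt_counts(model, n0, threshold, S, horizon)
  pmf <- as.numeric(cm[1, ]) / S
  names(pmf) <- 0:horizon
  list(pmf = pmf, censored = 1 - sum(pmf))
}

#' Assess a fitted model against the observed extinction process
#'
#' For each replicate, simulates `S` trajectories from the first retained
#' observation, builds the empirical fpt distribution at every observed
#' abundance threshold, and scores the observed passage times: the fpt
#' log-likelihood sums `log` of the simulated probability of each observed
#' fpt (probabilities of zero are floored at `1/(S+1)`), the fpt-AIC is
#' `-2 loglik + 2k` with `k` from the transition fit, and the RMSE is the
#' root mean squared difference between observed passage times and the mean
#' simulated passage time (over non-censored simulations), in days.
#'
#' @param fit a [fit_mle()] result, or a [pop_model()] with parameters set.
#' @param series an [abundance_series()] or list of them.
#' @param S simulations per replicate.
#' @param horizon simulation horizon in steps; default 10 times the series
#'   length.
#' @param seed optional integer seed.
#' @param keep_pmf if `TRUE`, store the full crossing-count matrices.
#' @return object of class `"fpt_assessment"`: a per-observation `table`
#'   (replicate, threshold, observed fpt, simulated probability, mean and
#'   censoring of simulated fpts), plus `loglik_fpt`, `aic_fpt`,
#'   `rmse_days`, `n_floored` and settings.
#' @export
fpt_assess <- function(fit, series, S = 1e5, horizon = NULL, seed = NULL,
                       keep_pmf = FALSE) {
  series <- .as_series_list(series)
  if (inherits(fit, "pop_fit")) {
    model <- fit$model
    k <- fit$k
  } else if (inherits(fit, "pop_model")) {
    model <- fit
    k <- n_free_params(fit)
  } else stop("fit must be a pop_fit or pop_model")
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  pmfs <- list()
  dt <- series[[1]]$dt
  for (s in series) {
    n <- .retained_counts(s)
    if (length(n) < 1 || n[1] < 1) {
      warning("replicate ", s$replicate, " has no usable observations")
      next
    }
    obs <- observed_fpts(s)
    hz <- if (is.null(horizon)) 10L * length(s$counts) else as.integer(horizon)
    cm <- .fpt_counts(model, n[1], obs$threshold, S, hz)
    tot <- rowSums(cm)
    mass <- cm[cbind(seq_len(nrow(obs)), obs$fpt + 1L)] / S
    mean_sim <- ifelse(tot > 0,
                       as.numeric(cm %*% (0:hz)) / tot, NA_real_)
    rows[[length(rows) + 1L]] <- data.frame(
      replicate = s$replicate,
      threshold = obs$threshold,
      fpt_obs = obs$fpt,
      prob_sim = mass,
      mean_fpt_sim = mean_sim,
      censored_frac = 1 - tot / S)
    if (keep_pmf) pmfs[[s$replicate]] <- cm / S
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab) || !nrow(tab)) stop("no usable replicates")
  floored <- tab$prob_sim <= 0
  loglik <- sum(log(pmax(tab$prob_sim, 1 / (S + 1))))
  ok <- is.finite(tab$mean_fpt_sim)
  rmse <- sqrt(mean((tab$fpt_obs[ok] - tab$mean_fpt_sim[ok])^2)) * dt
  structure(list(table = tab,
                 loglik_fpt = loglik,
                 aic_fpt = -2 * loglik + 2 * k,
                 rmse_days = rmse,
                 k = k, S = S, dt = dt,
                 n_floored = sum(floored),
                 pmf = if (keep_pmf) pmfs),
            class = "fpt_assessment")
}

#' @export
print.fpt_assessment <- function(x, ...) {
  cat("First-passage-time assessment (", nrow(x$table), "observed fpts,",
      x$S, "simulations )\n")
  cat("  fpt logLik", signif(x$loglik_fpt, 6),
      " fpt-AIC", signif(x$aic_fpt, 6),
      " RMSE", signif(x$rmse_days, 4), "days\n")
  if (x$n_floored)
    cat(" ", x$n_floored, "observed fpts had zero simulated mass (floored)\n")
  invisible(x)
}

#' First-passage-time likelihood and AIC
#'
#' Convenience wrapper around [fpt_assess()] returning just the fpt
#' log-likelihood and fpt-AIC.
#'
#' @inheritParams fpt_assess
#' @return list with `loglik_fpt` and `aic_fpt`.
#' @export
fpt_likelihood <- function(fit, series, S = 1e5, horizon = NULL,
                           seed = NULL) {
  a <- fpt_assess(fit, series, S = S, horizon = horizon, seed = seed)
  list(loglik_fpt = a$loglik_fpt, aic_fpt = a$aic_fpt)
}

#' Root mean square error of predicted passage times
#'
#' @param assessment an [fpt_assess()] result.
#' @return RMSE in days.
#' @export
fpt_rmse <- function(assessment) {
  stopifnot(inherits(assessment, "fpt_assessment"))
  assessment$rmse_days
}

## mean absorption time helper used by the MTE study: times to reach a state
## below one individual, vectorised over replicates, capped at `cap` steps
.absorption_times <- function(model, n0, reps, cap) {
  times <- rep(NA_integer_, reps)
  state <- rep(as.numeric(n0), reps)
  e <- w <- numeric(reps)
  idx <- seq_len(reps)
  t <- 0L
  while (length(idx) && t < cap) {
    st <- .sim_advance(state, e, w, model)
    state <- st$state; e <- st$e; w <- st$w
    t <- t + 1L
    dead <- state < 1
    if (any(dead)) {
      times[idx[dead]] <- t
      keep <- !dead
      state <- state[keep]; e <- e[keep]; w <- w[keep]; idx <- idx[keep]
    }
  }
  list(times = times, n_capped = length(idx), cap = cap)
}
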