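## The three computational experiments: the four-way model-comparison grid,
## the binomial measurement-error study, and the MTE-versus-MA study.

#' Candidate models for one model-set comparison
#'
#' Exactly one of the four model components is varied per comparison while
#' the others are fixed (Ricker density dependence, gamma transitions, the
#' demographic-plus-environmental variance model, no autocorrelation):
#' comparison 1 varies the density-dependence form, 2 the transition
#' family, 3 the autocorrelation mode, 4 the variance model.
#'
#' @param comparison integer 1-4.
#' @return named list of [pop_model()] skeletons.
#' @export
comparison_models <- function(comparison) {
  stopifnot(comparison %in% 1:4)
  switch(comparison,
    {
      forms <- c("ricker", "beverton_holt", "logistic", "gompertz",
                 "exponential")
      stats::setNames(lapply(forms, function(f)
        pop_model(f, "gamma", "dem_plus_env", "none")), forms)
    },
    {
      fams <- c("lognormal", "negative_binomial", "gamma")
      stats::setNames(lapply(fams, function(f)
        pop_model("ricker", f, "dem_plus_env", "none")), fams)
    },
    {
      modes <- c("none", "ar", "ma", "arma")
      stats::setNames(lapply(modes, function(m)
        pop_model("ricker", "gamma", "dem_plus_env", m)), modes)
    },
    {
      vars <- c("dem_plus_env", "no_dd_in_dem", "env_only", "dem_only")
      stats::setNames(lapply(vars, function(v)
        pop_model("ricker", "gamma", v, "none")), vars)
    })
}

#' Run one model-set comparison
#'
#' Fits every candidate model of the comparison to the same series by
#' maximum likelihood, assesses each with the simulated first-passage-time
#' likelihood, and tabulates fpt-AIC (with delta values relative to the
#' comparison minimum over converged fits) and RMSE.
#'
#' @param comparison integer 1-4, see [comparison_models()].
#' @param series an [abundance_series()] or list of them.
#' @param S simulations per replicate for the fpt assessment.
#' @param seed integer seed; model `i` uses `seed + i` so the table is
#'   reproducible.
#' @param starts optimiser starts per fit.
#' @param horizon fpt simulation horizon (default 10 times series length).
#' @return data frame with one row per candidate: `model`, `k`,
#'   `loglik_fpt`, `aic_fpt`, `delta_aic`, `rmse_days`, `converged`,
#'   `best`.
#' @export
run_comparison <- function(comparison, series, S = 1e5, seed = 1,
                           starts = 20, horizon = NULL) {
  grid <- comparison_models(comparison)
  rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    label <- names(grid)[i]
    fit <- tryCatch(fit_mle(series, grid[[i]], starts = starts,
                            seed = seed + i),
                    error = function(e) NULL)
    if (is.null(fit)) {
      rows[[i]] <- data.frame(model = label, k = n_free_params(grid[[i]]),
                              loglik_fpt = NA_real_, aic_fpt = NA_real_,
                              rmse_days = NA_real_, converged = FALSE)
      next
    }
    # common assessment seed across candidates: paired Monte-Carlo noise
    # cancels in the fpt-AIC differences
    a <- fpt_assess(fit, series, S = S, horizon = horizon,
                    seed = seed + 100L)
    rows[[i]] <- data.frame(model = label, k = fit$k,
                            loglik_fpt = a$loglik_fpt, aic_fpt = a$aic_fpt,
                            rmse_days = a$rmse_days,
                            converged = fit$converged)
  }
  df <- do.call(rbind, rows)
  ok <- df$converged & is.finite(df$aic_fpt)
  df$delta_aic <- df$aic_fpt - min(df$aic_fpt[ok])
  df$delta_aic[!ok] <- NA_real_
  cand <- which(ok & df$delta_aic <= 1e-8)
  df$best <- seq_len(nrow(df)) %in% cand[which.min(df$k[cand])]
  df
}

#' Measurement-error simulation study
#'
#' Determines how much of a fitted MA coefficient binomial sampling error
#' alone can produce.  For each parameter set, simulates abundance series
#' from the autocorrelation-free generator, rescales the counts by
#' `1/p_detect` (the unobserved volume), applies binomial observation
#' thinning with detection probability `p_detect`, fits the matching model
#' with an added MA term, and reports the mean and standard error of the
#' fitted MA coefficient.
#'
#' An externally observed MA coefficient is "explained by sampling error"
#' if it falls within about 2 standard errors of the reported mean
#' (see [sampling_error_explains()]).
#'
#' @param param_sets named list of generating [pop_model()]s with
#'   `autocorrelation = "none"`; defaults to the three microcosm-like sets
#'   in [study_presets()].
#' @param n_series simulated series per parameter set.
#' @param p_detect detection probability.
#' @param T,burn_in,dt series dimensions (samples, discarded samples,
#'   days between samples).
#' @param seed integer seed.
#' @param starts optimiser starts per fit.
#' @return data frame with `set`, `mean_theta`, `se_theta`, `n_fit`,
#'   `n_dropped`.
#' @export
measurement_error_study <- function(param_sets = NULL, n_series = 100,
                                    p_detect = 0.58, T = 150, burn_in = 35,
                                    dt = 4, seed = 1, starts = 8) {
  if (is.null(param_sets)) param_sets <- study_presets()$microcosm_sets
  rows <- vector("list", length(param_sets))
  for (j in seq_along(param_sets)) {
    gen <- param_sets[[j]]
    if (gen$autocorrelation != "none")
      stop("generating models must have autocorrelation = 'none'")
    if (gen$density_dependence != "ricker" || gen$params$b <= 0)
      stop("generating models must be Ricker with b > 0")
    n0 <- log(gen$params$r) / gen$params$b
    ma_model <- pop_model(gen$density_dependence, gen$transition,
                          gen$variance, "ma")
    th <- rep(NA_real_, n_series)
    for (i in seq_len(n_series)) {
      set.seed(seed + 1000L * j + i)
      s <- generate_series(model = gen, n0 = n0, T = T, burn_in = burn_in,
                           dt = dt)
      s$counts <- round(s$counts / p_detect)
      s <- binomial_thinning(s, p_detect)
      fit <- tryCatch(fit_mle(s, ma_model, starts = starts,
                              seed = seed + 2000L * j + i),
                      error = function(e) NULL)
      if (!is.null(fit) && fit$converged) th[i] <- fit$params[["theta"]]
    }
    th <- th[is.finite(th)]
    rows[[j]] <- data.frame(
      set = names(param_sets)[j],
      mean_theta = mean(th),
      se_theta = stats::sd(th) / sqrt(length(th)),
      n_fit = length(th),
      n_dropped = n_series - length(th))
  }
  do.call(rbind, rows)
}

#' Is an observed MA coefficient explained by sampling error?
#'
#' @param theta_obs externally estimated MA coefficient.
#' @param mean_theta,se_theta output of [measurement_error_study()].
#' @return `TRUE` if `theta_obs` lies within 2 standard errors of the mean.
#' @export
sampling_error_explains <- function(theta_obs, mean_theta, se_theta) {
  abs(theta_obs - mean_theta) <= 2 * se_theta
}

#' Mean time to extinction as a function of the MA coefficient
#'
#' Varies the MA coefficient over a grid (default 20 equally spaced values
#' from -0.9 to 0) while holding the other parameters of the base model
#' fixed, and estimates the mean time to extinction (absorption below one
#' individual) by forward simulation.  Replicates still alive at `cap`
#' steps contribute the cap (an underestimate); their number is reported
#' and a warning raised.
#'
#' @param theta_grid MA coefficient values.
#' @param base base preset, a list with `model` (an MA-mode
#'   [pop_model()]), `n0` and `dt`; defaults to `study_presets()$mte_base`.
#' @param n0 initial abundance override.
#' @param reps simulated trajectories per grid value.
#' @param cap per-replicate step cap.
#' @param seed integer seed; grid value `i` uses `seed + i`.
#' @return data frame with `theta`, `mte_steps`, `mte_days`, `n_capped`.
#' @export
mte_vs_ma_study <- function(theta_grid = seq(-0.9, 0, length.out = 20),
                            base = NULL, n0 = NULL, reps = 10000,
                            cap = 100000, seed = 1) {
  if (is.null(base)) base <- study_presets()$mte_base
  model <- base$model
  if (!model$autocorrelation %in% c("ma", "arma"))
    stop("base model must include an MA component")
  if (is.null(n0)) n0 <- base$n0
  dt <- if (!is.null(base$dt)) base$dt else 4
  rows <- vector("list", length(theta_grid))
  total_capped <- 0L
  for (i in seq_along(theta_grid)) {
    set.seed(seed + i)
    m <- set_params(model, list(theta = theta_grid[i]))
    ab <- .absorption_times(m, n0, reps, cap)
    times <- ab$times
    times[is.na(times)] <- cap
    total_capped <- total_capped + ab$n_capped
    rows[[i]] <- data.frame(theta = theta_grid[i],
                            mte_steps = mean(times),
                            mte_days = mean(times) * dt,
                            n_capped = ab$n_capped)
  }
  if (total_capped > 0)
    warning(total_capped, " replicates were still alive at the ", cap,
            "-step cap; their MTE contributions are underestimates")
  do.call(rbind, rows)
}
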