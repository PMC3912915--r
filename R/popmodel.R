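## Density-dependence forms, the one-step conditional mean/variance, and the
## model container shared by the whole package.

.dd_forms <- c("ricker", "beverton_holt", "gompertz", "logistic", "exponential")
.trans_families <- c("gamma", "lognormal", "negative_binomial")
.var_modes <- c("dem_plus_env", "no_dd_in_dem", "env_only", "dem_only")
.acf_modes <- c("none", "ar", "ma", "arma")

#' Density-dependent survival
#'
#' Per-capita survival multiplier `p(n)` as a function of the previous
#' abundance.  All forms are bounded in (0, 1]: the Ricker
#' (`exp(-b n)`) and logistic (`1 - b n`, clamped below) are
#' overcompensatory, the Beverton-Holt (`1 / (1 + b n)`) and Gompertz
#' (`exp(-b ln n)`, with `p = 1` for `n < 1`) undercompensatory, and the
#' exponential form (`p = 1`) is the density-independent null.
#'
#' @param n nonnegative abundance(s).
#' @param form density-dependence form.
#' @param b nonnegative per-individual density parameter.
#' @param clamp floor applied to the logistic form so survival stays positive.
#' @return survival probabilities, same length as `n`.
#' @examples
#' dd_survival(100, "beverton_holt", b = 0.01)  # 0.5
#' @export
dd_survival <- function(n, form = .dd_forms, b = 0, clamp = 1e-10) {
  form <- match.arg(form)
  if (any(n < 0)) stop("abundance must be nonnegative")
  if (length(b) != 1L || is.na(b) || b < 0) stop("b must be a nonnegative scalar")
  switch(form,
    ricker        = exp(-b * n),
    beverton_holt = 1 / (1 + b * n),
    gompertz      = ifelse(n < 1, 1, exp(-b * log(pmax(n, 1)))),
    logistic      = pmax(clamp, 1 - b * n),
    exponential   = rep(1, length(n))
  )
}

#' Construct a stochastic population model
#'
#' Bundles the four model components that are varied in the model
#' comparisons: the density-dependence form, the moment-matched transition
#' family, the variance model, and the autocorrelation structure on the
#' growth errors; together with their parameters.
#'
#' The one-step transition has conditional mean `mu = r * n * p(n)` where
#' `r` is the per-capita multiplication rate (the product of mean offspring
#' number and density-independent survival, which are not separately
#' identifiable) and conditional variance
#' `V = sigma_d2 * mu + sigma_e2 * mu^2` under the full
#' demographic-plus-environmental model.  `no_dd_in_dem` removes the
#' density-dependent survival factor from the demographic component
#' (`V = sigma_d2 * r * n + sigma_e2 * mu^2`); `env_only` and `dem_only`
#' keep a single component.
#'
#' @param density_dependence one of `"ricker"`, `"beverton_holt"`,
#'   `"gompertz"`, `"logistic"`, `"exponential"`.
#' @param transition transition family: `"gamma"`, `"lognormal"` or
#'   `"negative_binomial"`.
#' @param variance variance model: `"dem_plus_env"`, `"no_dd_in_dem"`,
#'   `"env_only"` or `"dem_only"`.
#' @param autocorrelation growth-error correlation structure: `"none"`,
#'   `"ar"`, `"ma"` or `"arma"`.
#' @param r per-capita multiplication rate, positive.
#' @param b density parameter, nonnegative (forced to 0 for the
#'   exponential form).
#' @param sigma_d2 demographic variance scale (per unit mean).
#' @param sigma_e2 environmental variance scale (dimensionless).
#' @param rho AR coefficient, `|rho| < 1` (forced to 0 unless mode is
#'   `"ar"`/`"arma"`).
#' @param theta MA coefficient, `|theta| < 1` (forced to 0 unless mode is
#'   `"ma"`/`"arma"`).
#' @return an object of class `"pop_model"`.
#' @examples
#' m <- pop_model("ricker", r = 1.8, b = 0.01, sigma_d2 = 1, sigma_e2 = 0.01)
#' conditional_mean(50, m)
#' @export
pop_model <- function(density_dependence = .dd_forms,
                      transition = .trans_families,
                      variance = .var_modes,
                      autocorrelation = .acf_modes,
                      r = 1, b = 0, sigma_d2 = 1, sigma_e2 = 0,
                      rho = 0, theta = 0) {
  density_dependence <- match.arg(density_dependence)
  transition <- match.arg(transition)
  variance <- match.arg(variance)
  autocorrelation <- match.arg(autocorrelation)
  if (r <= 0) stop("r must be positive")
  if (b < 0) stop("b must be nonnegative")
  if (sigma_d2 < 0 || sigma_e2 < 0) stop("variance scales must be nonnegative")
  if (abs(rho) >= 1 || abs(theta) >= 1) stop("|rho| and |theta| must be < 1")
  if (density_dependence == "exponential") b <- 0
  if (variance == "env_only") sigma_d2 <- 0
  if (variance == "dem_only") sigma_e2 <- 0
  if (autocorrelation %in% c("none", "ma")) rho <- 0
  if (autocorrelation %in% c("none", "ar")) theta <- 0
  structure(
    list(density_dependence = density_dependence,
         transition = transition,
         variance = variance,
         autocorrelation = autocorrelation,
         params = list(r = r, b = b, sigma_d2 = sigma_d2,
                       sigma_e2 = sigma_e2, rho = rho, theta = theta)),
    class = "pop_model")
}

#' @export
print.pop_model <- function(x, ...) {
  cat("Stochastic population model\n")
  cat("  density dependence:", x$density_dependence,
      " transition:", x$transition, "\n")
  cat("  variance:", x$variance, " autocorrelation:", x$autocorrelation,
      " (k =", n_free_params(x), "free parameters)\n")
  p <- unlist(x$params)
  cat("  params:", paste(names(p), signif(p, 4), sep = "=", collapse = "  "),
      "\n")
  invisible(x)
}

#' Names of the freely estimated parameters of a model
#'
#' @param model a [pop_model()].
#' @return character vector of parameter names, in fitting order.
#' @export
free_param_names <- function(model) {
  nm <- "r"
  if (model$density_dependence != "exponential") nm <- c(nm, "b")
  if (model$variance %in% c("dem_plus_env", "no_dd_in_dem", "dem_only"))
    nm <- c(nm, "sigma_d2")
  if (model$variance %in% c("dem_plus_env", "no_dd_in_dem", "env_only"))
    nm <- c(nm, "sigma_e2")
  if (model$autocorrelation %in% c("ar", "arma")) nm <- c(nm, "rho")
  if (model$autocorrelation %in% c("ma", "arma")) nm <- c(nm, "theta")
  nm
}

#' Number of free parameters (k) used in AIC/BIC
#'
#' Base parameters (`r`, and `b` except for the exponential form), plus the
#' variance parameters (two for `dem_plus_env`/`no_dd_in_dem`, one
#' otherwise), plus one per AR/MA coefficient.
#'
#' @inheritParams free_param_names
#' @return integer parameter count.
#' @export
n_free_params <- function(model) length(free_param_names(model))

#' Extract model parameters as a named vector
#' @inheritParams free_param_names
#' @param free_only if `TRUE`, return only the freely estimated parameters.
#' @export
model_params <- function(model, free_only = FALSE) {
  p <- unlist(model$params)
  if (free_only) p <- p[free_param_names(model)]
  p
}

#' Replace (a subset of) model parameters
#' @inheritParams free_param_names
#' @param params named vector or list of parameter values.
#' @return the updated model.
#' @export
set_params <- function(model, params) {
  params <- as.list(params)
  stopifnot(all(names(params) %in% names(model$params)))
  model$params[names(params)] <- params
  model
}

#' Conditional mean of the one-step transition
#'
#' `mu = r * n * p(n)`; zero exactly when `n = 0` (extinction is absorbing).
#'
#' @param n_prev previous abundance(s), nonnegative.
#' @param model a [pop_model()].
#' @return expected next abundance(s).
#' @export
conditional_mean <- function(n_prev, model) {
  model$params$r * n_prev *
    dd_survival(n_prev, model$density_dependence, model$params$b)
}

## Variance evaluated at an (possibly autocorrelation-adjusted) mean mu_eff.
## For no_dd_in_dem the demographic part is sigma_d2 * r * n (no p(n) factor);
## dividing mu_eff by p(n) keeps that behaviour under the adjusted mean.
.cond_var_at_mu <- function(n_prev, mu_eff, model) {
  p <- model$params
  switch(model$variance,
    dem_plus_env = p$sigma_d2 * mu_eff + p$sigma_e2 * mu_eff^2,
    no_dd_in_dem = p$sigma_d2 * mu_eff /
      dd_survival(n_prev, model$density_dependence, p$b) +
      p$sigma_e2 * mu_eff^2,
    env_only = p$sigma_e2 * mu_eff^2,
    dem_only = p$sigma_d2 * mu_eff)
}

#' Conditional variance of the one-step transition
#'
#' Under the full model `V = sigma_d2 * mu + sigma_e2 * mu^2`: the first
#' (demographic) term scales linearly with abundance when survival is
#' density independent, the second (environmental) term scales with the
#' squared expected abundance.  `no_dd_in_dem` replaces the demographic term
#' by `sigma_d2 * r * n`, removing the density-dependent survival factor.
#'
#' @inheritParams conditional_mean
#' @return variance of the next abundance.
#' @export
conditional_variance <- function(n_prev, model) {
  .cond_var_at_mu(n_prev, conditional_mean(n_prev, model), model)
}

#' Build a model from a configuration block
#'
#' Accepts the JSON-style configuration block used by the pipeline:
#' a list with entries `density_dependence`, `transition`, `variance`,
#' `autocorrelation` and optionally any parameter values.
#'
#' @param config named list (for example parsed from JSON).
#' @return a [pop_model()].
#' @export
model_from_config <- function(config) {
  known <- c("density_dependence", "transition", "variance", "autocorrelation",
             "r", "b", "sigma_d2", "sigma_e2", "rho", "theta")
  bad <- setdiff(names(config), known)
  if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "))
  do.call(pop_model, config)
}

#' Short descriptive label for a model
#' @inheritParams free_param_names
#' @export
model_label <- function(model) {
  paste(model$density_dependence, model$transition, model$variance,
        model$autocorrelation, sep = "+")
}
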