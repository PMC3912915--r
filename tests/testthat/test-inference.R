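test_that("transition likelihood matches a hand computation", {
  # two gamma transitions, worked out term by term
  s <- abundance_series(c(10, 8, 9))
  m <- pop_model("ricker", "gamma", "dem_plus_env", "none",
                 r = 1.5, b = 0.02, sigma_d2 = 1, sigma_e2 = 0.05)
  mu1 <- 1.5 * 10 * exp(-0.2); V1 <- mu1 + 0.05 * mu1^2
  mu2 <- 1.5 * 8 * exp(-0.16); V2 <- mu2 + 0.05 * mu2^2
  by_hand <- -(stats::dgamma(8, shape = mu1^2 / V1, scale = V1 / mu1,
                             log = TRUE) +
               stats::dgamma(9, shape = mu2^2 / V2, scale = V2 / mu2,
                             log = TRUE))
  expect_equal(neg_log_likelihood(s, m), by_hand, tolerance = 1e-10)
})

test_that("likelihood nests and factorises", {
  s <- generate_series("quasi_stationary", seed = 5)
  base <- ricker_dem_env()
  ma0 <- pop_model("ricker", "gamma", "dem_plus_env", "ma",
                   r = 1.8, b = 0.01, sigma_d2 = 1, sigma_e2 = 0.01,
                   theta = 0)
  expect_equal(neg_log_likelihood(s, base), neg_log_likelihood(s, ma0))
  # additivity over a split series (no autocorrelation: transitions are
  # conditionally independent)
  n <- s$counts
  a <- abundance_series(n[1:60]); b <- abundance_series(n[60:length(n)])
  expect_equal(neg_log_likelihood(list(a, b), base),
               neg_log_likelihood(s, base), tolerance = 1e-10)
})

test_that("an extinction observation is scored with the sub-one cell", {
  s <- abundance_series(c(6, 3, 0, 0))
  m <- pop_model("exponential", "gamma", "dem_plus_env", "none",
                 r = 0.8, sigma_d2 = 1, sigma_e2 = 0.02)
  mu1 <- 4.8; V1 <- mu1 + 0.02 * mu1^2
  mu2 <- 2.4; V2 <- mu2 + 0.02 * mu2^2
  by_hand <- -(stats::dgamma(3, mu1^2 / V1, scale = V1 / mu1, log = TRUE) +
               stats::pgamma(1, mu2^2 / V2, scale = V2 / mu2, log.p = TRUE))
  expect_equal(neg_log_likelihood(s, m), by_hand, tolerance = 1e-10)
})

test_that("parameter count k matches the model grid", {
  expect_equal(n_free_params(ricker_dem_env()), 4)
  expect_equal(n_free_params(
    pop_model("ricker", "gamma", "dem_plus_env", "ma")), 5)
  expect_equal(n_free_params(
    pop_model("ricker", "gamma", "dem_plus_env", "ar")), 5)
  expect_equal(n_free_params(
    pop_model("ricker", "gamma", "dem_plus_env", "arma")), 6)
  expect_equal(n_free_params(
    pop_model("exponential", "gamma", "dem_plus_env", "none")), 3)
  expect_equal(n_free_params(
    pop_model("ricker", "gamma", "env_only", "none")), 3)
  expect_equal(n_free_params(
    pop_model("ricker", "gamma", "dem_only", "none")), 3)
  expect_equal(n_free_params(
    pop_model("ricker", "gamma", "no_dd_in_dem", "none")), 4)
})

test_that("near-noise-free dynamics pin down r and b", {
  gen <- pop_model("ricker", "gamma", "dem_plus_env", "none",
                   r = 1.3, b = 0.01, sigma_d2 = 1e-6, sigma_e2 = 1e-7)
  s <- generate_series(model = gen, n0 = 5, T = 40, burn_in = 0, seed = 9)
  f <- fit_mle(s, pop_model("ricker", "gamma", "dem_plus_env", "none"),
               starts = 8, seed = 1)
  expect_lt(abs(f$params[["r"]] - 1.3) / 1.3, 1e-3)
  expect_lt(abs(f$params[["b"]] - 0.01) / 0.01, 1e-3)
})

test_that("a nested model never beats the model containing it", {
  base <- pop_model("ricker", "gamma", "dem_plus_env", "none")
  full <- pop_model("ricker", "gamma", "dem_plus_env", "ma")
  for (i in 1:8) {
    s <- generate_series("quasi_stationary", seed = 600 + i)
    f0 <- fit_mle(s, base, starts = 6, seed = i)
    f1 <- fit_mle(s, full, starts = 6, seed = i)
    expect_gte(f1$loglik, f0$loglik - 1e-4)
  }
})

test_that("fits are reproducible under a fixed seed", {
  s <- generate_series("quasi_stationary", seed = 77)
  m <- ricker_dem_env()
  f1 <- fit_mle(s, m, starts = 5, seed = 42)
  f2 <- fit_mle(s, m, starts = 5, seed = 42)
  expect_identical(f1$params, f2$params)
  expect_equal(f1$aic, -2 * f1$loglik + 2 * f1$k)
  expect_equal(f1$bic, -2 * f1$loglik + f1$k * log(f1$n_transitions))
})

test_that("information criteria tabulate deltas with ties broken by k", {
  mk_fit <- function(ll, k) structure(
    list(loglik = ll, k = k, aic = -2 * ll + 2 * k,
         bic = -2 * ll + k * log(100),
         model = ricker_dem_env()), class = "pop_fit")
  tab <- information_criteria(list(mk_fit(-10, 4), mk_fit(-11, 4)),
                              labels = c("a", "b"))
  expect_equal(tab$aic, c(28, 30))
  expect_equal(tab$delta_aic, c(0, 2))
  expect_true(tab$best[1])
  # equal loglik, different k: smaller k preferred, delta gap of 2
  tab2 <- information_criteria(list(mk_fit(-10, 4), mk_fit(-10, 5)),
                               labels = c("small", "big"))
  expect_equal(tab2$delta_aic, c(0, 2))
  expect_true(tab2$best[1])
})

test_that("interval machinery brackets the estimate", {
  s <- generate_series("quasi_stationary", seed = 15)
  f <- fit_mle(s, ricker_dem_env(), starts = 6, seed = 2)
  ci <- confint(f, parm = c("r", "b"))
  expect_true(all(ci[, "lower"] <= ci[, "estimate"] &
                  ci[, "estimate"] <= ci[, "upper"]))
  pci <- profile_ci(f, s, parm = "r")
  expect_lt(pci["r", "lower"], f$params[["r"]])
  expect_gt(pci["r", "upper"], f$params[["r"]])
  # profile interval at the 2-SE deviance level contains values whose
  # profiled likelihood is within 2 units of the optimum
  expect_gt(pci["r", "upper"] - pci["r", "lower"], 0)
})
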