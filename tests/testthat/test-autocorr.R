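test_that("innovation filter reproduces the defining recursion", {
  # MA step: a_2 = theta * w_1
  f <- innovation_filter(c(0.1, 0), c(0, 0), theta = -0.5)
  expect_equal(f$adjusted, c(0, -0.05))
  expect_equal(f$innovations, c(0.1, 0.05))
  # AR on the raw deviation
  f <- innovation_filter(c(0.2, 0.2, 0.2), c(0, 0, 0), rho = 0.5)
  expect_equal(f$adjusted, c(0, 0.1, 0.1))
  expect_equal(f$innovations, c(0.2, 0.1, 0.1))
  # no structure: identity on deviations
  x <- rnorm(10); m <- rnorm(10)
  f <- innovation_filter(x, m)
  expect_identical(f$adjusted, m)
  expect_identical(f$innovations, f$deviations)
  expect_error(innovation_filter(1, 1), "length at least 2")
})

test_that("adjusted moments scale the mean and recompute the variance", {
  m <- pop_model("exponential", "gamma", "dem_plus_env", "ma", r = 1,
                 sigma_d2 = 1, sigma_e2 = 0, theta = -0.5)
  am <- adjusted_moments(10, e_prev = 0, w_prev = 0.1, m)
  expect_equal(am$mu, 10 * exp(-0.05))
  expect_equal(am$V, am$mu)  # pure demographic, recomputed at mu*
  # zero lags leave the moments untouched
  am0 <- adjusted_moments(10, 0, 0, m)
  expect_equal(am0$mu, conditional_mean(10, m))
  expect_equal(am0$V, conditional_variance(10, m))
  # a negative MA coefficient pulls the mean towards the expectation
  for (w in c(-0.3, 0.2)) {
    am <- adjusted_moments(10, 0, w, m)
    expect_equal(sign(log(am$mu) - log(10)), sign(-0.5 * w))
  }
})

test_that("two-species reduction gives the stated ARMA(2,1) coefficients", {
  # uncoupled: composite noise is exactly (1 - b22 L) W1
  red <- var_to_arma(two_species_system(0.5, 0, 0, 0.8))
  expect_equal(red$phi1, 1.3)
  expect_equal(red$phi2, -0.4)
  expect_equal(red$theta1, -0.8)
  red2 <- var_to_arma(two_species_system(0.9, -0.3, 0.5, 0.9, 1, 1))
  expect_equal(red2$phi1, 1.8)
  expect_equal(red2$phi2, -0.15 - 0.81)
  # invertibility of the matched MA root
  expect_lt(abs(red2$theta1), 1)
  expect_error(two_species_system(1.2, 0, 0, 0.5), "non-stationary")
})

test_that("the MA magnitude is maximised when the partner follows a random
           walk", {
  b22_grid <- seq(0.1, 1, by = 0.05)
  th <- vapply(b22_grid, function(b22)
    abs(var_to_arma(two_species_system(0.5, 0.3, -0.3, b22, 1, 1))$theta1),
    0)
  expect_equal(b22_grid[which.max(th)], 1)
})

test_that("simulated focal-species dynamics match the analytic ARMA(2,1)", {
  sys <- two_species_system(0.6, 0.3, -0.4, 0.7, 1, 1)
  red <- var_to_arma(sys)
  set.seed(21)
  x <- simulate_two_species(sys, 1e5)[, "x1"]
  # stats::ARMAacf as the independent autocorrelation oracle
  th_acf <- stats::ARMAacf(ar = c(red$phi1, red$phi2), ma = red$theta1,
                           lag.max = 5)[-1]
  s_acf <- stats::acf(x, lag.max = 5, plot = FALSE)$acf[-1, 1, 1]
  expect_lt(max(abs(th_acf - s_acf)), 3 * 5 / sqrt(1e5))
  # coefficients recovered by the Hannan-Rissanen estimator
  co <- estimate_arma21(x)
  ase <- arma21_asymptotic_se(red$phi1, red$phi2, red$theta1, 1e5)
  expect_lt(abs(co[["phi1"]] - red$phi1), 4 * ase[["phi1"]] + 0.005)
  expect_lt(abs(co[["phi2"]] - red$phi2), 4 * ase[["phi2"]] + 0.005)
  # zero noise from equilibrium stays at equilibrium
  sys0 <- two_species_system(0.6, 0.3, -0.4, 0.7, 0, 0)
  x0 <- simulate_two_species(sys0, 10, init = c(0, 0))
  expect_equal(max(abs(x0)), 0)
})

test_that("an uncoupled focal species is AR(1) with coefficient b11", {
  sys <- two_species_system(0.55, 0, 0, 0.4, 1, 1)
  set.seed(22)
  x <- simulate_two_species(sys, 1e5)[, "x1"]
  r1 <- stats::acf(x, lag.max = 1, plot = FALSE)$acf[2, 1, 1]
  expect_lt(abs(r1 - 0.55), 3 / sqrt(1e5) * 3)
})

test_that("identifiability screen rejects near root cancellation", {
  # shared AR/MA root (1 - 0.8z + 0.15z^2 = (1-0.5z)(1-0.3z), MA root at 2):
  # the coefficients are unidentifiable and the SEs blow up
  se_bad <- arma21_asymptotic_se(0.8, -0.15, -0.5, 1e5)
  se_ok <- arma21_asymptotic_se(0.8, -0.15, 0.5, 1e5)
  expect_gt(max(se_bad[c("phi1", "phi2")]), 0.05)
  expect_lt(max(se_ok[c("phi1", "phi2")]), 0.01)
  set.seed(3)
  sys <- random_stationary_system()
  red <- attr(sys, "reduction")
  se <- arma21_asymptotic_se(red$phi1, red$phi2, red$theta1, 1e5)
  expect_lte(max(se[c("phi1", "phi2")]), 0.008)
})
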