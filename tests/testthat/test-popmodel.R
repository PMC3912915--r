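test_that("survival forms match their closed forms and stay in (0, 1]", {
  expect_equal(dd_survival(50, "ricker", b = 0), 1)
  expect_equal(dd_survival(100, "beverton_holt", b = 0.01), 0.5)
  expect_equal(dd_survival(exp(1), "gompertz", b = 1), exp(-1))
  expect_equal(dd_survival(60, "logistic", b = 0.02), 1e-10)  # clamped
  expect_equal(dd_survival(1000, "exponential"), 1)
  n <- c(0, 0.5, 1, 7, 300)
  for (form in c("ricker", "beverton_holt", "gompertz", "logistic",
                 "exponential")) {
    p <- dd_survival(n, form, b = 0.03)
    expect_true(all(p > 0 & p <= 1), info = form)
  }
  expect_error(dd_survival(-1, "ricker", b = 1), "nonnegative")
  expect_error(dd_survival(1, "ricker", b = -1), "nonnegative")
})

test_that("conditional mean is r n p(n), zero only at extinction", {
  expect_equal(conditional_mean(1, pop_model("ricker", r = 2, b = log(2))), 1)
  expect_equal(conditional_mean(10, pop_model("exponential", r = 1.5)), 15)
  for (form in c("ricker", "beverton_holt", "gompertz", "logistic",
                 "exponential"))
    expect_equal(conditional_mean(0, pop_model(form, r = 2, b = 0.01)), 0)
})

test_that("variance components scale as specified", {
  m_dem <- pop_model("exponential", variance = "dem_only", r = 1,
                     sigma_d2 = 1)
  expect_equal(conditional_variance(5, m_dem), 5)  # pure demographic
  m_env <- pop_model("exponential", variance = "env_only", r = 1,
                     sigma_e2 = 0.04)
  expect_equal(conditional_variance(10, m_env), 4)  # pure environmental
  # removing density dependence from the demographic part: p(n) factor gone
  m_full <- pop_model("ricker", variance = "dem_plus_env", r = 2, b = log(2),
                      sigma_d2 = 1, sigma_e2 = 0)
  m_nodd <- pop_model("ricker", variance = "no_dd_in_dem", r = 2, b = log(2),
                      sigma_d2 = 1, sigma_e2 = 0)
  expect_equal(conditional_variance(1, m_full), 1)
  expect_equal(conditional_variance(1, m_nodd), 2)
})

test_that("demographic variance is exactly proportional to n only without
           density dependence", {
  m <- pop_model("exponential", variance = "dem_only", r = 1.2, sigma_d2 = 0.7)
  n <- c(1, 5, 20, 80)
  expect_equal(conditional_variance(n, m) / n,
               rep(conditional_variance(1, m), 4))
  # the two demographic conventions converge at low abundance where p -> 1
  for (form in c("ricker", "beverton_holt", "gompertz")) {
    m1 <- pop_model(form, variance = "dem_plus_env", r = 1.5, b = 0.05,
                    sigma_d2 = 1, sigma_e2 = 0.01)
    m2 <- pop_model(form, variance = "no_dd_in_dem", r = 1.5, b = 0.05,
                    sigma_d2 = 1, sigma_e2 = 0.01)
    n_small <- 1e-3
    expect_equal(conditional_variance(n_small, m1),
                 conditional_variance(n_small, m2), tolerance = 1e-3)
  }
})

test_that("over- vs undercompensation: Ricker mean peaks at 1/b, Beverton-Holt
           and Gompertz means are nondecreasing", {
  b <- 0.02
  n <- seq(1, 400, by = 0.5)
  mu_r <- conditional_mean(n, pop_model("ricker", r = 2, b = b))
  expect_equal(n[which.max(mu_r)], 1 / b, tolerance = 0.02)
  for (form in c("beverton_holt", "gompertz")) {
    mu <- conditional_mean(n, pop_model(form, r = 2, b = b))
    expect_true(all(diff(mu) >= -1e-12), info = form)
  }
})

test_that("model constructor enforces component coherence", {
  m <- pop_model("exponential", variance = "env_only", autocorrelation = "ar",
                 r = 1, b = 5, sigma_d2 = 3, rho = 0.4, theta = 0.2)
  expect_equal(m$params$b, 0)          # exponential has no b
  expect_equal(m$params$sigma_d2, 0)   # env_only drops demographic scale
  expect_equal(m$params$theta, 0)      # ar mode drops theta
  expect_error(pop_model(r = -1), "positive")
  expect_error(pop_model(rho = 1.2, autocorrelation = "ar"), "< 1")
  cfg <- list(density_dependence = "gompertz", transition = "lognormal",
              variance = "dem_only", autocorrelation = "ma",
              r = 1.4, b = 0.2, theta = -0.3)
  m2 <- model_from_config(cfg)
  expect_s3_class(m2, "pop_model")
  expect_equal(m2$params$theta, -0.3)
  expect_error(model_from_config(c(cfg, list(bogus = 1))), "unknown")
})
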