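test_that("trajectory simulation is the deterministic map without noise and
           absorbs below one individual", {
  m <- pop_model("exponential", "gamma", "dem_plus_env", "none",
                 r = 0.5, sigma_d2 = 0, sigma_e2 = 0)
  expect_equal(simulate_trajectory(m, 8, 10),
               c(8, 4, 2, 1, rep(0, 7)))  # absorbed at 0 thereafter
  mr <- pop_model("ricker", "gamma", "dem_plus_env", "none",
                  r = 2, b = 0.01, sigma_d2 = 0, sigma_e2 = 0)
  tr <- simulate_trajectory(mr, 30, 3)
  expect_equal(tr[2], 2 * 30 * exp(-0.3))
  # seeded runs are bit-identical
  ms <- ricker_dem_env()
  expect_identical(simulate_trajectory(ms, 50, 40, seed = 5),
                   simulate_trajectory(ms, 50, 40, seed = 5))
})

test_that("first passage time follows its definition, censored as NA", {
  expect_equal(first_passage_time(c(10, 5, 3, 7), 4), 2L)
  expect_equal(first_passage_time(c(10, 5, 3, 7), 10), 0L)
  expect_true(is.na(first_passage_time(c(10, 5, 3, 7), 1)))
  expect_error(first_passage_time(c(10, 5), 0), "positive")
})

test_that("observed passage times cover every observed abundance", {
  s <- abundance_series(c(10, 5, 3, 7))
  o <- observed_fpts(s)
  expect_equal(o$threshold, c(10, 7, 5, 3))
  expect_equal(o$fpt, c(0L, 1L, 1L, 2L))
  o2 <- observed_fpts(abundance_series(c(9, 6, 2)))
  expect_equal(o2$fpt, c(0L, 1L, 2L))
  o3 <- observed_fpts(abundance_series(c(5, 5, 5)))  # duplicates collapse
  expect_equal(dim(o3), c(1L, 2L))
  expect_equal(o3$fpt, 0L)
  # passage times are antitone in the threshold
  set.seed(8)
  s4 <- abundance_series(round(runif(40, 1, 60)))
  o4 <- observed_fpts(s4)  # thresholds sorted decreasing
  expect_true(all(diff(o4$fpt) >= 0))
})

test_that("fpt distribution is a point mass for deterministic dynamics and
           conserves probability", {
  m <- pop_model("exponential", "gamma", "dem_plus_env", "none",
                 r = 0.5, sigma_d2 = 0, sigma_e2 = 0)
  d <- fpt_distribution(m, 8, threshold = 0.9, S = 50, horizon = 10)
  expect_equal(unname(d$pmf[["4"]]), 1)  # 8,4,2,1,<1 at t = 4
  expect_equal(sum(d$pmf) + d$censored, 1)
  # quasi-stationary model rarely crosses a low threshold: censored mass
  ds <- fpt_distribution(ricker_dem_env(), 59, threshold = 5, S = 200,
                         horizon = 50, seed = 3)
  expect_equal(sum(ds$pmf) + ds$censored, 1)
  expect_gt(ds$censored, 0.5)
})

test_that("empirical fpt distribution agrees with the matrix-power oracle", {
  model <- oracle_model()
  horizon <- 120
  pmf_exact <- exact_fpt_pmf(model, n0 = 12, n_max = 30, horizon = horizon)
  emp <- fpt_distribution(model, 12, threshold = 0.9, S = 2e4,
                          horizon = horizon, seed = 11)
  expect_lt(max(abs(emp$pmf - pmf_exact)), 0.02)
  mean_emp <- sum(emp$pmf * 0:horizon) / sum(emp$pmf)
  mean_exact <- sum(pmf_exact * 0:horizon) / sum(pmf_exact)
  expect_lt(abs(mean_emp - mean_exact) / mean_exact, 0.02)
})

test_that("fpt likelihood floors zero-mass observations at 1/(S+1)", {
  # deterministic decline: all simulated mass at the deterministic fpts
  m <- pop_model("exponential", "gamma", "dem_plus_env", "none",
                 r = 0.5, sigma_d2 = 0, sigma_e2 = 0)
  s <- abundance_series(c(8, 6, 2, 0))  # observed fpts differ from 8,4,2,...
  a <- fpt_assess(m, s, S = 99, horizon = 20)
  # thresholds 8, 6, 2: sim trajectory 8,4,2,1,0 crosses 8 at 0, 6 at 1,
  # 2 at 2; observed fpts are 0, 1, 2 -> all matched, no floor
  expect_equal(a$n_floored, 0)
  s2 <- abundance_series(c(8, 8, 8, 6))
  a2 <- fpt_assess(m, s2, S = 99, horizon = 20)
  # observed fpt of threshold 6 is 3, but simulations cross at 1: floored
  expect_gt(a2$n_floored, 0)
  expect_equal(a2$loglik_fpt,
               log(1) + log(1 / 100),  # threshold 8 at t=0 (mass 1) + floor
               tolerance = 1e-12)
})

test_that("assessment summaries have the stated structure", {
  set.seed(2)
  ss <- make_replicates(synthetic_presets()$declining$model, n0 = 400,
                        n_rep = 2, seed_base = 40)
  f <- fit_mle(ss, pop_model("exponential", "gamma", "dem_plus_env", "none"),
               starts = 5, seed = 1)
  a <- fpt_assess(f, ss, S = 500, seed = 9)
  expect_s3_class(a, "fpt_assessment")
  expect_equal(a$aic_fpt, -2 * a$loglik_fpt + 2 * f$k)
  expect_gte(a$rmse_days, 0)
  expect_true(all(a$table$censored_frac >= 0 & a$table$censored_frac <= 1))
  # rmse in days: residuals in steps scaled by the 4-day interval
  ok <- is.finite(a$table$mean_fpt_sim)
  expect_equal(a$rmse_days,
               sqrt(mean((a$table$fpt_obs[ok] - a$table$mean_fpt_sim[ok])^2)) * 4)
  l <- fpt_likelihood(f, ss, S = 500, seed = 9)
  expect_equal(l$aic_fpt, a$aic_fpt)
  expect_equal(fpt_rmse(a), a$rmse_days)
})
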