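# shared fixtures: all synthetic, built in code at test time

ricker_dem_env <- function(...) {
  pop_model("ricker", "gamma", "dem_plus_env", "none",
            r = 1.8, b = 0.01, sigma_d2 = 1, sigma_e2 = 0.01, ...)
}

# exact first-passage pmf to extinction (state 0) for a truncated
# integer-state chain with negative-binomial transitions, by transition
# matrix powers -- the independent oracle for the empirical fpt machinery
exact_fpt_pmf <- function(model, n0, n_max, horizon) {
  P <- matrix(0, n_max + 1, n_max + 1)
  P[1, 1] <- 1
  for (i in 1:n_max) {
    mu <- conditional_mean(i, model)
    V <- conditional_variance(i, model)
    mm <- match_negbinom(mu, V)
    pr <- stats::dnbinom(0:(n_max - 1), size = mm$size, prob = mm$prob)
    P[i + 1, 1:n_max] <- pr
    P[i + 1, n_max + 1] <- 1 - sum(pr)
  }
  v <- rep(0, n_max + 1)
  v[n0 + 1] <- 1
  pmf <- numeric(horizon + 1)
  cum_prev <- v[1]
  for (t in 1:horizon) {
    v <- as.vector(v %*% P)
    pmf[t + 1] <- v[1] - cum_prev
    cum_prev <- v[1]
  }
  pmf
}

# the negative-binomial declining model used with the oracle: stays far
# below the truncation bound
oracle_model <- function() {
  pop_model("exponential", "negative_binomial", "dem_plus_env", "none",
            r = 0.65, sigma_d2 = 1, sigma_e2 = 0.04)
}

make_replicates <- function(model, n0, n_rep = 3, T = 150, burn_in = 35,
                            seed_base = 0) {
  lapply(seq_len(n_rep), function(j)
    generate_series(model = model, n0 = n0, T = T, burn_in = burn_in,
                    seed = seed_base + j, replicate = paste0("r", j)))
}
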