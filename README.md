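# popfpt

Stochastic population models and first-passage-time prediction of
extinction risk.

Population viability analysis (PVA) fits stochastic models of population
growth to abundance time series and uses them to assess extinction risk.
Most fitting criteria score models on the abundances themselves; `popfpt`
additionally scores them on what PVA actually asks of a model — the
distribution of **first passage times** (fpt) below each observed
abundance — so that model assumptions can be ranked by how well they
predict the extinction process.  The package is aimed at quantitative
ecologists working with single-species counts at regular sampling
intervals (its defaults emulate *Daphnia*-style microcosms counted every
4 days), and at anyone studying how community interactions leave
detectable traces in single-species series.

## The model

Abundance evolves in discrete time with conditional mean and variance

    mu = r * n * p(n)
    V  = sigma_d^2 * mu + sigma_e^2 * mu^2

where `r` is the per-capita multiplication rate, `p(n)` a
density-dependent survival in (0, 1] (Ricker `exp(-b n)`, Beverton–Holt
`1/(1+b n)`, Gompertz `exp(-b ln n)`, logistic `1 - b n`, or the
density-independent null `p = 1`), `sigma_d^2` scales demographic
stochasticity (linear in the mean) and `sigma_e^2` environmental
stochasticity (quadratic).  The transition distribution is a gamma,
log-normal, or negative binomial matched exactly to `(mu, V)`.

Growth errors may carry AR/MA/ARMA structure on the log scale,

    a_t = m_t + rho * e_{t-1} + theta * w_{t-1},

which rescales both variance components through the adjusted mean.  These
terms are more than a statistical patch: for two interacting species with
linear log-scale dynamics `X(t) = B X(t-1) + W(t)`, the focal species
marginally follows an ARMA(2,1) with `phi1 = b11 + b22`,
`phi2 = b12 b21 - b11 b22`, and an MA coefficient maximised when the
partner species follows a random walk (`var_to_arma()` computes the
reduction).  Autocorrelation in a single-species series is thus a proxy
for unobserved community interactions.

Models are fitted by maximum likelihood on the one-step transitions
(`fit_mle`), then assessed by simulation (`fpt_assess`): `S` trajectories
from the first observation give an empirical fpt distribution at every
observed abundance threshold, yielding an fpt log-likelihood, an fpt-AIC
(`-2 loglik + 2k`), and the RMSE of predicted passage times in days.

## Worked example

Generate three declining synthetic microcosms, fit the density-independent
model, assess its extinction predictions, and run the density-dependence
model comparison:

```r
library(popfpt)
series <- lapply(1:3, function(j)
  generate_series("declining", seed = 100 + j, replicate = paste0("m", j)))

fit <- fit_mle(series, pop_model("exponential", "gamma", "dem_plus_env", "none"),
               seed = 1)
fit
#> Maximum-likelihood fit: exponential+gamma+dem_plus_env+none
#>   logLik -169.633  k = 3  AIC 345.265  BIC 351.788
#>        r sigma_d2 sigma_e2
#>   0.9091   1.1340   0.0070

assess <- fpt_assess(fit, series, S = 1e4, seed = 2)
assess
#> First-passage-time assessment ( 65 observed fpts, 10000 simulations )
#>   fpt logLik -159.328  fpt-AIC 324.656  RMSE 12.37 days

tab <- run_comparison(1, series, S = 1e3, seed = 3, starts = 8)
tab[, c("model", "k", "aic_fpt", "delta_aic", "rmse_days", "best")]
#>           model k aic_fpt delta_aic rmse_days  best
#> 1        ricker 4   338.5    14.200     12.52 FALSE
#> 2 beverton_holt 4   335.5    11.292     12.24 FALSE
#> 3      logistic 4   330.0     5.728     12.52 FALSE
#> 4      gompertz 4   325.9     1.669     12.23 FALSE
#> 5   exponential 3   324.3     0.000     11.93  TRUE
```

The fitted multiplication rate (0.909, true 0.93) says the population
shrinks about 9% per 4-day step; the fpt-AIC table ranks the candidate
density-dependence forms by how well their simulated passage-time
distributions explain the observed ones (`delta_aic = 0` marks the best
model — here correctly the density-independent generator), and the RMSE
column reports the mean passage-time error in days.

Other entry points: `mte_vs_ma_study()` (mean time to extinction as a
function of the MA coefficient), `measurement_error_study()` (how much MA
signature binomial observation error alone induces),
`binomial_thinning()`, `generate_community_series()`, and
`run_pipeline()` for a config-driven fit/assess/compare run writing JSON
and CSV artifacts.  The methods vignette
(`vignettes/popfpt-methods.Rmd`) documents the model, the numerical
conventions, and every preset.

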