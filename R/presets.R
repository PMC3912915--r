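## Versioned constants: the synthetic-data presets used throughout the
## package's simulation studies.  Magnitudes (tens to hundreds of
## individuals, 4-day sampling, 150 retained samples after a 140-day
## burn-in) emulate Daphnia-microcosm data; the parameter values are the
## package's own synthetic stand-ins, not estimates from any experiment.

#' Synthetic regime presets
#'
#' Two dynamical regimes: `quasi_stationary` fluctuates about the carrying
#' capacity `K = log(r)/b` of a Ricker model with demographic and
#' environmental variance (the small-population paradigm), and `declining`
#' follows density-independent decline with mean one-step ratio 0.93 (the
#' declining-population paradigm), reaching extinction with high probability
#' within the series length.
#'
#' @return named list of presets, each with `model`, `n0`, `T`, `burn_in`
#'   and `dt` (days).
#' @export
synthetic_presets <- function() {
  list(
    quasi_stationary = list(
      model = pop_model("ricker", "gamma", "dem_plus_env", "none",
                        r = 1.8, b = 0.01, sigma_d2 = 1, sigma_e2 = 0.01),
      n0 = log(1.8) / 0.01,  # carrying capacity, ~58.8
      T = 150, burn_in = 35, dt = 4),
    declining = list(
      model = pop_model("exponential", "gamma", "dem_plus_env", "none",
                        r = 0.93, sigma_d2 = 1, sigma_e2 = 0.01),
      n0 = 400, T = 150, burn_in = 35, dt = 4)
  )
}

#' Presets for the simulation studies
#'
#' * `microcosm_sets`: three quasi-stationary Ricker parameter sets standing
#'   in for the three simple-community microcosms in the measurement-error
#'   study.
#' * `mte_base`: the extinction-prone Ricker+MA base model for the mean
#'   time-to-extinction study (small carrying capacity and substantial
#'   environmental variance, so that absorption is observable at simulation
#'   scale); `n0` is its carrying capacity.
#' * `comparison_recovery`: a declining Gompertz generator
#'   (undercompensatory decline from 200 towards an equilibrium near 15
#'   individuals) used by the density-dependence model-recovery study; its
#'   log-linear survival separates it from the other density-dependence
#'   forms over the sampled abundance range.
#' * `ma_recovery`: a declining density-independent generator with a
#'   moving-average term (`theta = -0.4`) used by the
#'   autocorrelation-recovery study; without density dependence the MA
#'   structure appears undiluted in the growth increments.
#'
#' @return named list of presets.
#' @export
study_presets <- function() {
  list(
    microcosm_sets = list(
      m1 = pop_model("ricker", "gamma", "dem_plus_env", "none",
                     r = 1.8, b = 0.01, sigma_d2 = 1, sigma_e2 = 0.01),
      m2 = pop_model("ricker", "gamma", "dem_plus_env", "none",
                     r = 1.6, b = 0.008, sigma_d2 = 1, sigma_e2 = 0.01),
      m3 = pop_model("ricker", "gamma", "dem_plus_env", "none",
                     r = 2.0, b = 0.012, sigma_d2 = 1, sigma_e2 = 0.01)),
    mte_base = list(
      model = pop_model("ricker", "gamma", "dem_plus_env", "ma",
                        r = 1.4, b = 0.03, sigma_d2 = 1, sigma_e2 = 0.05,
                        theta = 0),
      n0 = log(1.4) / 0.03,  # ~11.2
      dt = 4),
    comparison_recovery = list(
      model = pop_model("gompertz", "gamma", "dem_plus_env", "none",
                        r = 1.5, b = 0.15, sigma_d2 = 1, sigma_e2 = 0.01),
      n0 = 200, T = 150, burn_in = 0, dt = 4),
    ma_recovery = list(
      model = pop_model("exponential", "gamma", "dem_plus_env", "ma",
                        r = 0.93, sigma_d2 = 1, sigma_e2 = 0.01,
                        theta = -0.4),
      n0 = 800, T = 150, burn_in = 35, dt = 4)
  )
}
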