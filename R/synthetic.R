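## Generators for synthetic microcosm-like data: every stage of the analysis
## is testable without external data.

#' Generate a synthetic abundance series
#'
#' Simulates a trajectory from a regime preset (see [synthetic_presets()])
#' or a user-supplied model, discards the burn-in (35 samples at the default
#' 4-day interval, i.e. 140 days of transient dynamics), and returns the
#' retained samples as an [abundance_series()].  Extinct states are recorded
#' as 0.
#'
#' @param regime `"quasi_stationary"` or `"declining"`; ignored when
#'   `model` is given.
#' @param model optional [pop_model()] used as the generator.
#' @param n0 initial abundance (defaults to the preset's).
#' @param T number of retained samples.
#' @param burn_in number of discarded leading samples.
#' @param dt sampling interval in days.
#' @param seed optional integer seed.
#' @param replicate replicate identifier.
#' @return an [abundance_series()] of length `T`.
#' @export
generate_series <- function(regime = c("quasi_stationary", "declining"),
                            model = NULL, n0 = NULL, T = 150, burn_in = 35,
                            dt = 4, seed = NULL, replicate = "r1") {
  if (is.null(model)) {
    preset <- synthetic_presets()[[match.arg(regime)]]
    model <- preset$model
    if (is.null(n0)) n0 <- preset$n0
  }
  if (is.null(n0)) stop("n0 required when a custom model is given")
  if (!is.null(seed)) set.seed(seed)
  traj <- simulate_trajectory(model, n0, horizon = burn_in + T - 1)
  if (length(traj) < burn_in + T)  # absorbed early; pad with zeros
    traj <- c(traj, rep(0, burn_in + T - length(traj)))
  abundance_series(traj[(burn_in + 1):(burn_in + T)], dt = dt,
                   replicate = replicate)
}

#' Generate a focal-species series from a two-species community
#'
#' Simulates the two-species log-scale system and exponentiates the focal
#' species about a mean log-abundance `level`, producing single-species
#' abundance data whose growth errors carry the ARMA structure induced by
#' the hidden interacting species (see [var_to_arma()]).
#'
#' @param sys a [two_species_system()].
#' @param T number of retained samples.
#' @param level mean log-abundance of the focal species.
#' @param dt sampling interval in days.
#' @param seed optional integer seed.
#' @param replicate replicate identifier.
#' @return an [abundance_series()] of length `T`.
#' @export
generate_community_series <- function(sys, T = 150, level = log(50), dt = 4,
                                      seed = NULL, replicate = "r1") {
  x <- simulate_two_species(sys, steps = T, seed = seed)
  abundance_series(exp(x[, "x1"] + level), dt = dt, replicate = replicate)
}

#' Binomial observation thinning
#'
#' Replaces each (integer) count by a binomial draw with detection
#' probability `p_detect`, emulating partial observation of the microcosm
#' volume; `p_detect = 1` is the identity.
#'
#' @param series an [abundance_series()] with integer counts.
#' @param p_detect detection probability in (0, 1].
#' @param seed optional integer seed.
#' @return the thinned [abundance_series()].
#' @export
binomial_thinning <- function(series, p_detect, seed = NULL) {
  stopifnot(inherits(series, "abundance_series"),
            p_detect > 0, p_detect <= 1)
  if (any(series$counts != round(series$counts)))
    stop("binomial thinning requires integer counts")
  if (!is.null(seed)) set.seed(seed)
  if (p_detect == 1) return(series)
  thinned <- stats::rbinom(length(series$counts), series$counts, p_detect)
  abundance_series(thinned, series$times, series$replicate, series$dt)
}
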