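#' Simulated rater population model
#'
#' Describes a population of raters whose judgments are noisy readouts of a
#' latent consonance surface. Each trial's latent value is
#' `surface(coords) + participant intercept + trial noise`, mapped to a 1-7
#' Likert response by clipping the latent z-value to `[-2.5, 2.5]`,
#' rescaling affinely to `[1, 7]`, and rounding. Intercepts are Gaussian
#' with standard deviation `participant_sd`; trial noise is Gaussian with
#' standard deviation `noise_sd`. Only intercept heterogeneity is modeled,
#' so within-participant z-scoring exactly removes the participant effect.
#'
#' @param surface Function mapping stimulus coordinates (numeric vector or
#'   matrix rows) to latent consonance in z-units; typically a
#'   median-normalized composite-model profile (see
#'   [composite_surface()]).
#' @param participant_sd Between-participant intercept spread, z-units
#'   (default 0.3).
#' @param noise_sd Within-participant trial noise, z-units (default 1.0).
#' @param n_participants Number of raters (default 200).
#' @param trials_per_participant Trials per rater (default 40).
#' @param bass_range MIDI range for the roving bass, sampled uniformly per
#'   trial (default `c(55, 65)`, G3-F4).
#' @param likert Monotone response map from latent values to ratings
#'   (default [likert_map()], producing integers 1-7; pass e.g. `identity`
#'   for an unquantized readout in recovery studies).
#' @return An object of class `rater_model`.
#' @export
rater_model <- function(surface, participant_sd = 0.3, noise_sd = 1.0,
                        n_participants = 200, trials_per_participant = 40,
                        bass_range = c(55, 65), likert = likert_map) {
  stopifnot(is.function(surface), participant_sd >= 0, noise_sd >= 0,
            n_participants >= 1, trials_per_participant >= 1,
            is.function(likert))
  structure(list(surface = surface, participant_sd = participant_sd,
                 noise_sd = noise_sd, n_participants = n_participants,
                 trials_per_participant = trials_per_participant,
                 bass_range = bass_range, likert = likert),
            class = "rater_model")
}

#' Default Likert response map
#'
#' Maps a latent consonance value in z-units to a 1-7 rating: the latent
#' value is clipped to `[-2.5, 2.5]`, rescaled affinely to `[1, 7]`, and
#' rounded to the nearest integer.
#'
#' @param z Numeric latent values.
#' @return Integer ratings in 1..7.
#' @export
likert_map <- function(z) {
  z <- pmin(pmax(z, -2.5), 2.5)
  as.integer(round(1 + (z + 2.5) * 6 / 5))
}

#' Simulate a dense-rating dataset
#'
#' Emulates the dense-rating paradigm: each trial samples the stimulus
#' interval uniformly from `coord_range` and the bass pitch uniformly from
#' the model's `bass_range`, then generates a 1-7 rating from the rater
#' model. Deterministic given `seed`.
#'
#' @param model A [rater_model()].
#' @param coord_range Length-2 interval range in semitones (default
#'   `c(0, 15)`).
#' @param seed Integer seed.
#' @return Data frame with columns `participant`, `interval`, `bass`,
#'   `rating` (integer in 1..7).
#' @export
simulate_dense_ratings <- function(model, coord_range = c(0, 15), seed = 1) {
  stopifnot(inherits(model, "rater_model"), length(coord_range) == 2L,
            coord_range[1] < coord_range[2])
  local_rng(seed, {
    P <- model$n_participants
    Tn <- model$trials_per_participant
    n <- P * Tn
    participant <- rep(seq_len(P), each = Tn)
    intercept <- rep(stats::rnorm(P, 0, model$participant_sd), each = Tn)
    interval <- stats::runif(n, coord_range[1], coord_range[2])
    bass <- stats::runif(n, model$bass_range[1], model$bass_range[2])
    latent <- model$surface(interval) + intercept +
      stats::rnorm(n, 0, model$noise_sd)
    data.frame(participant = participant, interval = interval, bass = bass,
               rating = model$likert(latent))
  })
}

#' Simulate a fine-tuning rating study
#'
#' Dense ratings on a narrow 0.5-semitone window centered on a prototypical
#' interval (e.g. 3.9, 8.9, or 12 semitones), as used for probing tuning
#' preferences; downstream analysis conventionally smooths these with a
#' 0.035-semitone bandwidth.
#'
#' @param model A [rater_model()].
#' @param center Window center in semitones.
#' @param halfwidth Window half-width (default 0.25).
#' @param seed Integer seed.
#' @return As [simulate_dense_ratings()].
#' @export
simulate_tuning_study <- function(model, center, halfwidth = 0.25, seed = 1) {
  if (center <= halfwidth) stop("'center' must exceed 'halfwidth'", call. = FALSE)
  simulate_dense_ratings(model, coord_range = center + c(-1, 1) * halfwidth,
                         seed = seed)
}

#' Latent consonance surface from the composite model
#'
#' Precomputes the median-normalized composite-model profile for dyads of
#' the given timbre over an interval range and returns a fast linear
#' interpolant, suitable as the `surface` of a [rater_model()].
#'
#' @param timbres A [timbre()] or list of two timbres.
#' @param range Interval range (default `c(0, 15)`).
#' @param bass Bass pitch used for the model evaluation (MIDI, default 60).
#' @param n_grid Precomputation grid size (default 1000).
#' @param params A [composite_params()].
#' @param standardize Divide by the profile's standard deviation to force
#'   unit spread (default `FALSE`: a genuinely flat surface, e.g. pure
#'   tones on a tuning window, should stay flat relative to rating noise).
#' @return A function `interval -> latent z`.
#' @export
composite_surface <- function(timbres = timbre("harmonic"), range = c(0, 15),
                              bass = 60, n_grid = 1000,
                              params = composite_params(),
                              standardize = FALSE) {
  grid <- seq(range[1], range[2], length.out = n_grid)
  raw <- score_profile("composite", grid, bass = bass, timbres = timbres,
                       params = params)
  vals <- normalize_profile(raw)
  if (standardize && stats::sd(vals) > 0) vals <- vals / stats::sd(vals)
  stats::approxfun(grid, vals, rule = 2)
}
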