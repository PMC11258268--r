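#' Parameters of the composite consonance model
#'
#' The composite model combines the revised interference model and the
#' pitch-clarity harmonicity model additively:
#' `score = w_interference * dissonance_revised + w_harmonicity * harmonicity_hp`,
#' with fixed weights of -1 (interference) and +0.837 (harmonicity). Higher
#' scores mean more consonant. Weights are applied to the raw component
#' outputs; median normalization (see [normalize_profile()]) is applied to
#' profiles, not to components.
#'
#' The harmonic matching template is precomputed here so that repeated
#' scoring (dense profiles, optimization) avoids rebuilding it.
#'
#' @param w_interference Weight on [dissonance_revised()] (default -1).
#' @param w_harmonicity Weight on [harmonicity_hp()] (default +0.837).
#' @param dissonance Revised-kernel parameters; a [dissonance_params()].
#' @param template_n_harmonics,template_roll_off Harmonic template shape.
#' @param smear_sd,resolution Pitch-class smearing parameters; see
#'   [pc_spectrum()].
#' @return An object of class `composite_params`.
#' @export
composite_params <- function(w_interference = -1, w_harmonicity = 0.837,
                             dissonance = dissonance_params(),
                             template_n_harmonics = 12,
                             template_roll_off = 3,
                             smear_sd = 6.83, resolution = 1200) {
  stopifnot(is.finite(w_interference), is.finite(w_harmonicity),
            inherits(dissonance, "dissonance_params"))
  template <- harmonic_template(template_n_harmonics, template_roll_off,
                                smear_sd, resolution)
  structure(list(w_interference = w_interference,
                 w_harmonicity = w_harmonicity,
                 dissonance = dissonance,
                 smear_sd = smear_sd, resolution = resolution,
                 template = template),
            class = "composite_params")
}

#' Composite consonance score of a spectrum
#'
#' @param spectrum A [tone_spectrum()].
#' @param params A [composite_params()] object.
#' @return Scalar consonance score (higher = more consonant).
#' @export
#' @examples
#' cp <- composite_params()
#' sp <- chord_spectrum(chord_spec(60, 12), timbre("harmonic"))
#' composite_score(sp, cp)
composite_score <- function(spectrum, params = composite_params()) {
  stopifnot(inherits(params, "composite_params"))
  d <- dissonance_revised(spectrum, params$dissonance)
  pcs <- pc_spectrum(spectrum, params$smear_sd, params$resolution)
  h <- harmonicity_hp(virtual_pitch_profile(pcs, params$template))
  params$w_interference * d + params$w_harmonicity * h
}

#' Median-normalize a vector of model outputs
#'
#' Subtracts the median, mimicking how raters calibrate their scale usage to
#' the stimuli of an experiment: the output has median 0.
#'
#' @param values Nonempty numeric vector.
#' @return `values - median(values)`.
#' @export
normalize_profile <- function(values) {
  if (length(values) == 0L) stop("'values' must be nonempty", call. = FALSE)
  values - stats::median(values)
}

#' Evaluate a consonance model over a grid of dyad (or chord) intervals
#'
#' Convenience wrapper: for each interval (or row of intervals), builds the
#' chord spectrum above a fixed bass and scores it with the requested model.
#' This yields the raw (unsmoothed) model consonance profile.
#'
#' @param model One of `"composite"`, `"hk_original"`, `"hk_revised"`,
#'   `"hp"`, `"milne"`, or a function `spectrum -> score`.
#' @param intervals Numeric vector (dyads) or matrix/data frame with one
#'   column per interval dimension (larger chords).
#' @param bass Bass pitch, MIDI (default 60, middle C).
#' @param timbres A [timbre()] or list of timbres, one per chord tone.
#' @param params A [composite_params()] (used by `"composite"`,
#'   `"hk_revised"`, `"hp"` and `"milne"` for their respective settings).
#' @return Numeric vector of raw model scores. For the interference-only
#'   models the sign convention is dissonance (higher = rougher); callers
#'   comparing against behavior typically negate or use `"composite"`.
#' @export
score_profile <- function(model, intervals, bass = 60,
                          timbres = timbre("harmonic"),
                          params = composite_params()) {
  if (is.function(model)) {
    score_fun <- model
  } else {
    model <- match.arg(model, c("composite", "hk_original", "hk_revised",
                                "hp", "milne"))
    score_fun <- switch(model,
      composite = function(sp) composite_score(sp, params),
      hk_original = dissonance_original,
      hk_revised = function(sp) dissonance_revised(sp, params$dissonance),
      hp = function(sp) {
        pcs <- pc_spectrum(sp, params$smear_sd, params$resolution)
        harmonicity_hp(virtual_pitch_profile(pcs, params$template))
      },
      milne = function(sp) {
        pcs <- pc_spectrum(sp, params$smear_sd, params$resolution)
        harmonicity_milne(virtual_pitch_profile(pcs, params$template))
      })
  }
  if (is.null(dim(intervals))) intervals <- matrix(intervals, ncol = 1)
  intervals <- as.matrix(intervals)
  vapply(seq_len(nrow(intervals)), function(k) {
    sp <- chord_spectrum(chord_spec(bass, intervals[k, ]), timbres)
    score_fun(sp)
  }, numeric(1))
}
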