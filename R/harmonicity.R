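#' Pitch-class spectrum of a tone spectrum
#'
#' Projects a spectrum into the circular pitch-class domain `[0, 12)`
#' semitones. Each partial is mapped to its pitch class (MIDI pitch modulo
#' 12) and deposited as a circular Gaussian bump of standard deviation
#' `smear_sd` cents, scaled by the partial's linear amplitude; contributions
#' from different partials add. Gaussians are truncated at +/- 6 standard
#' deviations, with mass wrapped around the octave.
#'
#' @param spectrum A [tone_spectrum()] with at least one partial.
#' @param smear_sd Gaussian smearing standard deviation in cents
#'   (default 6.83).
#' @param resolution Bins per octave (default 1200, i.e. 1-cent bins).
#' @return An object of class `pc_spectrum`: list with `weights`
#'   (nonnegative vector of length `resolution`) and `resolution`.
#' @export
pc_spectrum <- function(spectrum, smear_sd = 6.83, resolution = 1200) {
  if (is.null(spectrum) || nrow(spectrum) == 0L) {
    stop("spectrum must contain at least one partial", call. = FALSE)
  }
  bins_per_semitone <- resolution / 12
  sd_bins <- smear_sd / 100 * bins_per_semitone
  pc <- freq_to_midi(spectrum$frequency) %% 12
  pos <- pc * bins_per_semitone  # 0-based bin coordinate, circular
  weights <- numeric(resolution)
  halfwidth <- max(1L, ceiling(6 * sd_bins))
  offsets <- (-halfwidth):halfwidth
  wrap_ok <- length(offsets) < resolution  # window indices unique after wrap
  for (k in seq_along(pos)) {
    center <- pos[k]
    bins <- round(center) + offsets
    d <- bins - center
    g <- spectrum$amplitude[k] * exp(-d^2 / (2 * sd_bins^2))
    idx <- (bins %% resolution) + 1L
    if (wrap_ok) {
      weights[idx] <- weights[idx] + g
    } else {
      acc <- rowsum(g, idx)
      ii <- as.integer(rownames(acc))
      weights[ii] <- weights[ii] + acc[, 1]
    }
  }
  structure(list(weights = weights, resolution = resolution),
            class = "pc_spectrum")
}

#' Harmonic template in pitch-class space
#'
#' The pitch-class spectrum of an idealized harmonic complex tone with its
#' fundamental at pitch class 0: `n_harmonics` harmonics rolling off at
#' `roll_off` dB/octave, smeared as in [pc_spectrum()]. Used as the matching
#' template for virtual pitch estimation.
#'
#' @param n_harmonics Number of template harmonics (default 12).
#' @param roll_off Template roll-off in dB/octave (default 3).
#' @inheritParams pc_spectrum
#' @return A `pc_spectrum`.
#' @export
harmonic_template <- function(n_harmonics = 12, roll_off = 3,
                              smear_sd = 6.83, resolution = 1200) {
  if (n_harmonics < 1) stop("'n_harmonics' must be >= 1", call. = FALSE)
  tone <- make_tone(timbre("harmonic", n_harmonics = n_harmonics,
                           roll_off = roll_off),
                    midi_to_freq(0))  # fundamental at pitch class 0
  pc_spectrum(tone, smear_sd = smear_sd, resolution = resolution)
}

#' Virtual pitch strength profile
#'
#' The cosine similarity between a chord's pitch-class spectrum and every
#' circular transposition of a harmonic template. Entry `k` (0-based) is the
#' similarity to the template transposed up by `k` bins; values lie in
#' `[0, 1]` for nonnegative spectra.
#'
#' @param chord_pc A `pc_spectrum` of the chord.
#' @param template A `pc_spectrum` template with the same resolution.
#' @param method `"fft"` (circular cross-correlation via FFT, default) or
#'   `"direct"` (explicit loop over shifts; the independent oracle).
#' @return An object of class `virtual_pitch_profile`: list with
#'   `strengths` (length `resolution`) and `resolution`.
#' @export
virtual_pitch_profile <- function(chord_pc, template,
                                  method = c("fft", "direct")) {
  method <- match.arg(method)
  stopifnot(inherits(chord_pc, "pc_spectrum"), inherits(template, "pc_spectrum"))
  if (chord_pc$resolution != template$resolution) {
    stop("resolutions of chord and template must match", call. = FALSE)
  }
  a <- chord_pc$weights
  b <- template$weights
  n <- length(a)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("zero-mass pitch-class spectrum", call. = FALSE)
  if (method == "fft") {
    # dot(a, shift(b, k)) for all k via circular cross-correlation
    cross <- Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)),
                           inverse = TRUE)) / n
  } else {
    cross <- vapply(0:(n - 1), function(k) {
      shifted <- b[((seq_len(n) - 1 - k) %% n) + 1]
      sum(a * shifted)
    }, numeric(1))
  }
  strengths <- pmax(cross, 0) / (na * nb)
  structure(list(strengths = pmin(strengths, 1), resolution = n),
            class = "virtual_pitch_profile")
}

#' Harmonicity as pitch clarity (KL divergence from uniform)
#'
#' Normalizes the virtual pitch strength profile to a probability
#' distribution `P` and returns its Kullback-Leibler divergence from the
#' uniform distribution, `KL(P || U) = log(n) - H(P)` in nats. A profile
#' with one clear virtual pitch has low entropy and hence high harmonicity;
#' a uniform profile scores 0. The `0 * log(0)` convention is 0.
#'
#' @param profile A [virtual_pitch_profile()].
#' @return Nonnegative harmonicity score in nats.
#' @export
harmonicity_hp <- function(profile) {
  stopifnot(inherits(profile, "virtual_pitch_profile"))
  s <- profile$strengths
  total <- sum(s)
  if (total <= 0) stop("profile has zero total mass", call. = FALSE)
  p <- s / total
  nz <- p > 0
  entropy <- -sum(p[nz] * log(p[nz]))
  log(length(p)) - entropy
}

#' Harmonicity as maximum virtual pitch strength
#'
#' Returns the height of the highest peak of the virtual pitch strength
#' profile; in `[0, 1]` for cosine-similarity profiles.
#'
#' @param profile A [virtual_pitch_profile()].
#' @return Maximum strength.
#' @export
harmonicity_milne <- function(profile) {
  stopifnot(inherits(profile, "virtual_pitch_profile"))
  if (length(profile$strengths) == 0L) stop("empty profile", call. = FALSE)
  max(profile$strengths)
}
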