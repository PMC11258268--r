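#' Parameters of the revised interference model
#'
#' Three parameters control the revised dissonance model:
#'
#' * `p`, the slow-beat boundary in critical-bandwidth units: below this
#'   distance, beating is slow enough to be heard as pleasant.
#' * `q`, the slow-beat pleasantness: the strength of the negative
#'   (pleasant) dissonance contributed by slow beats.
#' * `r`, the amplitude exponent: pairwise interference is weighted by
#'   `(A_i * A_j)^(r/2)`, so `r = 2` weights by intensity (the original
#'   model) and `r = 1` by amplitude.
#'
#' Defaults are the numerically optimized values `p = 0.096`, `q = 1.632`,
#' `r = 1.359`.
#'
#' @param p Slow-beat boundary (> 0; `p = 0` degenerates to the original
#'   kernel).
#' @param q Slow-beat pleasantness (>= 0).
#' @param r Amplitude exponent (> 0).
#' @return An object of class `dissonance_params`.
#' @export
dissonance_params <- function(p = 0.096, q = 1.632, r = 1.359) {
  if (p < 0) stop("'p' must be >= 0", call. = FALSE)
  if (q < 0) stop("'q' must be >= 0", call. = FALSE)
  if (r <= 0) stop("'r' must be > 0", call. = FALSE)
  structure(list(p = p, q = q, r = r), class = "dissonance_params")
}

#' Critical bandwidth distance between two frequencies
#'
#' Expresses the separation of two partials in units of the auditory
#' critical bandwidth at their mean frequency:
#' `x = |f2 - f1| / (1.72 * ((f1 + f2) / 2)^0.65)`.
#'
#' @param f1,f2 Frequencies in Hz (positive; vectorized).
#' @return Distances in critical-bandwidth units (symmetric in arguments;
#'   0 iff `f1 == f2`).
#' @export
critical_bandwidth_distance <- function(f1, f2) {
  if (any(f1 <= 0) || any(f2 <= 0)) {
    stop("frequencies must be positive", call. = FALSE)
  }
  abs(f2 - f1) / (1.72 * ((f1 + f2) / 2)^0.65)
}

#' Original pairwise dissonance kernel
#'
#' The parametric approximation to the Hutchinson-Knopoff dissonance curve:
#' `D(x) = (4 * x * exp(1 - 4 * x))^2`, where `x` is the critical-bandwidth
#' distance between two partials. `D(0) = 0`, the unique maximum is
#' `D(0.25) = 1`, and `D -> 0` as `x -> Inf`.
#'
#' @param x Critical-bandwidth distances (>= 0; vectorized).
#' @return Relative dissonance values.
#' @export
kernel_original <- function(x) {
  if (any(x < 0)) stop("'x' must be >= 0", call. = FALSE)
  (4 * x * exp(1 - 4 * x))^2
}

#' Revised pairwise dissonance kernel with slow-beat pleasantness
#'
#' For `x < p` the original kernel is blended with a negative (pleasant)
#' slow-beat term:
#' `D*(x) = (x/p) D(x) - q (1 - x/p) (1 + sin(2 pi x/p - pi/2))`,
#' and `D*(x) = D(x)` for `x >= p`. The kernel is continuous at `x = 0`
#' (both terms vanish) and at `x = p`. Negative values encode the
#' pleasantness of slow beats. With `p = 0` the revised kernel coincides
#' with [kernel_original()].
#'
#' @param x Critical-bandwidth distances (>= 0; vectorized).
#' @param params A [dissonance_params()] object.
#' @return Signed dissonance values.
#' @export
kernel_revised <- function(x, params = dissonance_params()) {
  if (any(x < 0)) stop("'x' must be >= 0", call. = FALSE)
  stopifnot(inherits(params, "dissonance_params"))
  D <- kernel_original(x)
  if (params$p == 0) return(D)
  below <- x < params$p
  if (any(below)) {
    xb <- x[below] / params$p
    D[below] <- xb * D[below] -
      params$q * (1 - xb) * (1 + sin(2 * pi * xb - pi / 2))
  }
  D
}

# shared pairwise aggregation over all partial pairs
aggregate_pairs <- function(spectrum, kernel, r) {
  if (is.null(spectrum) || nrow(spectrum) == 0L) {
    stop("spectrum must contain at least one partial", call. = FALSE)
  }
  n <- nrow(spectrum)
  denom <- sum(spectrum$amplitude^r)
  if (n == 1L) return(0)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  f1 <- spectrum$frequency[idx[, 1]]
  f2 <- spectrum$frequency[idx[, 2]]
  a1 <- spectrum$amplitude[idx[, 1]]
  a2 <- spectrum$amplitude[idx[, 2]]
  x <- critical_bandwidth_distance(f1, f2)
  sum((a1 * a2)^(r / 2) * kernel(x)) / denom
}

#' Original interference (roughness) score of a spectrum
#'
#' Sums [kernel_original()] contributions over all pairs of partials,
#' weighted by the product of their amplitudes (intensity weighting), and
#' normalizes by the total squared amplitude:
#' `sum_{i<j} A_i A_j D(x_ij) / sum_k A_k^2`.
#' The score is invariant to partial ordering and to global amplitude
#' scaling, and is 0 for a single partial or exact unisons.
#'
#' @param spectrum A [tone_spectrum()].
#' @return Nonnegative dissonance score.
#' @export
dissonance_original <- function(spectrum) {
  aggregate_pairs(spectrum, kernel_original, r = 2)
}

#' Revised interference score of a spectrum
#'
#' As [dissonance_original()] but with the slow-beat kernel
#' [kernel_revised()] and amplitude-exponent weighting:
#' `sum_{i<j} (A_i A_j)^(r/2) D*(x_ij) / sum_k A_k^r`.
#' Reduces to the original model when `r = 2`, `q = 0` and `p -> 0`. The
#' score may be negative (net pleasant slow beating) and is invariant to
#' global amplitude scaling for any `r`.
#'
#' @param spectrum A [tone_spectrum()].
#' @param params A [dissonance_params()] object.
#' @return Signed dissonance score.
#' @export
dissonance_revised <- function(spectrum, params = dissonance_params()) {
  stopifnot(inherits(params, "dissonance_params"))
  aggregate_pairs(spectrum, function(x) kernel_revised(x, params), params$r)
}
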