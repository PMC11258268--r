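#' Peak-picking configuration
#'
#' Controls the derivative-based peak detector used on smoothed consonance
#' profiles. The profile is approximated by a cubic smoothing spline with
#' `spline_df` equivalent degrees of freedom (near-interpolating at the
#' default 100 on a 1000-point grid). Candidate peaks are grid points where
#' the spline's first derivative changes sign from positive to negative and
#' its second derivative is below `-curvature_frac * range(f)`; troughs are
#' defined symmetrically. Adjacent peaks are merged (keeping the taller)
#' when the lowest intervening trough is shallower than `alpha * range(f)`;
#' remaining peaks must be *sharp*: within `sharpness_window` on each side
#' there must exist a point at least `beta * range(f)` below the peak.
#'
#' All depth thresholds are fractions of the profile's range, making the
#' detector invariant to affine rescaling of the values. The 0.5-semitone
#' sharpness and reliability windows are used unscaled on all profile
#' ranges (on a 0.5-semitone tuning window they then span the whole
#' profile, so the sharpness test reduces to a depth test against each
#' side's minimum); set `rescale_windows = TRUE` to shrink them
#' proportionally to `range / 15` instead.
#'
#' @param spline_df Equivalent degrees of freedom of the smoothing spline
#'   (default 100; capped at `n - 4`).
#' @param alpha Merge depth threshold, fraction of range (default 0.01).
#' @param beta Sharpness threshold, fraction of range (default 0.01 for
#'   behavioral profiles; 0.05 is used for deterministic model profiles).
#' @param curvature_frac Curvature threshold as a fraction of range
#'   (default 1/20).
#' @param sharpness_window Half-window for the sharpness test, semitones
#'   (default 0.5).
#' @param reliability_window Matching half-window for bootstrap peak
#'   reliability, semitones (default 0.5).
#' @param reliability_threshold Minimum fraction of bootstrap replicates
#'   reproducing a peak (default 0.95).
#' @param rescale_windows Rescale the two windows by `range / 15` for
#'   profiles narrower than 15 semitones (default `FALSE`).
#' @return An object of class `peak_pick_config`.
#' @export
peak_pick_config <- function(spline_df = 100, alpha = 0.01, beta = 0.01,
                             curvature_frac = 1 / 20,
                             sharpness_window = 0.5,
                             reliability_window = 0.5,
                             reliability_threshold = 0.95,
                             rescale_windows = FALSE) {
  stopifnot(spline_df > 0, alpha > 0, beta > 0, beta <= 1,
            curvature_frac > 0, sharpness_window > 0,
            reliability_window > 0, reliability_threshold > 0)
  structure(list(spline_df = spline_df, alpha = alpha, beta = beta,
                 curvature_frac = curvature_frac,
                 sharpness_window = sharpness_window,
                 reliability_window = reliability_window,
                 reliability_threshold = reliability_threshold,
                 rescale_windows = isTRUE(rescale_windows)),
            class = "peak_pick_config")
}

window_scale <- function(config, x) {
  if (!config$rescale_windows) return(1)
  min(1, diff(range(x)) / 15)
}

#' Detect peaks in a smoothed consonance profile
#'
#' Implements the detector described in [peak_pick_config()]: smoothing
#' spline fit, derivative sign changes with a curvature condition, trough
#' detection, shallow-trough merging, and the two-sided sharpness filter.
#' A degenerate (constant) profile yields no peaks.
#'
#' @param profile A `consonance_profile` data frame (first column the grid
#'   coordinate, `value` column the profile), or a numeric vector of values
#'   when `x` is given.
#' @param config A [peak_pick_config()].
#' @param x Optional grid coordinates when `profile` is a bare vector.
#' @return Data frame of class `peak_set` with columns `location` and
#'   `height`, sorted by location.
#' @export
find_peaks <- function(profile, config = peak_pick_config(), x = NULL) {
  if (is.data.frame(profile)) {
    x <- profile[[1]]
    y <- profile$value
  } else {
    y <- profile
    if (is.null(x)) stop("'x' is required for vector input", call. = FALSE)
  }
  ok <- is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(y)
  empty <- data.frame(location = numeric(), height = numeric())
  class(empty) <- c("peak_set", "data.frame")
  if (n < 10L) stop("profile must have at least 10 points", call. = FALSE)
  if (diff(range(y)) == 0) return(empty)
  df <- min(config$spline_df, n - 4)
  fit <- suppressWarnings(stats::smooth.spline(x, y, df = df))
  f <- stats::predict(fit, x)$y
  d1 <- stats::predict(fit, x, deriv = 1)$y
  d2 <- stats::predict(fit, x, deriv = 2)$y
  rng <- diff(range(f))
  if (rng == 0) return(empty)
  i <- seq_len(n - 1)
  peak_idx <- which(d1[i] > 0 & d1[i + 1] < 0 &
                    d2[i] < -rng * config$curvature_frac)
  trough_idx <- which(d1[i] < 0 & d1[i + 1] > 0 &
                      d2[i] > rng * config$curvature_frac)
  if (length(peak_idx) == 0L) return(empty)

  # merge peaks not separated by deep enough troughs, keeping the taller
  peaks <- sort(peak_idx)
  repeat {
    if (length(peaks) < 2L) break
    merged <- FALSE
    for (k in seq_len(length(peaks) - 1L)) {
      p1 <- peaks[k]; p2 <- peaks[k + 1L]
      between <- trough_idx[trough_idx > p1 & trough_idx < p2]
      # lowest trough between the peaks; when the valley is too flat to
      # qualify as a trough under the curvature test, fall back to the
      # lowest intervening point so wide flat valleys still separate peaks
      t_min <- if (length(between)) min(f[between])
               else min(f[(p1 + 1L):max(p2 - 1L, p1 + 1L)])
      if (min(f[p1], f[p2]) - t_min < config$alpha * rng) {
        drop <- if (f[p1] >= f[p2]) k + 1L else k
        peaks <- peaks[-drop]
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }

  # two-sided sharpness filter
  w <- config$sharpness_window * window_scale(config, x)
  sharp <- vapply(peaks, function(p) {
    left <- which(x >= x[p] - w & x <= x[p])
    right <- which(x >= x[p] & x <= x[p] + w)
    any(f[p] - f[left] >= config$beta * rng) &&
      any(f[p] - f[right] >= config$beta * rng)
  }, logical(1))
  peaks <- peaks[sharp]
  out <- data.frame(location = x[peaks], height = f[peaks])
  out <- out[order(out$location), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peak_set", "data.frame")
  out
}

#' Bootstrap reliability and location intervals for detected peaks
#'
#' Runs [find_peaks()] on each bootstrap replicate profile and, for each
#' reference peak, counts the fraction of replicates containing at least
#' one peak within `reliability_window` semitones. Peaks reproduced in more
#' than `reliability_threshold` of replicates are retained; their location
#' confidence interval is `mean +/- 1.96 * sd` of the matched (nearest)
#' replicate peak locations.
#'
#' @param replicates Matrix of replicate profiles (grid points x
#'   replicates), e.g. the `"replicates"` attribute of
#'   [bootstrap_profile()], or a list of profile value vectors.
#' @param grid Grid coordinates of the profiles.
#' @param reference_peaks A `peak_set` from the full-sample profile.
#' @param config A [peak_pick_config()].
#' @param ci_mult Half-width multiplier for the location interval.
#' @return A `peak_set` with columns `location`, `height`, `reliability`,
#'   `ci_low`, `ci_high`, containing only reliable peaks.
#' @export
peak_reliability <- function(replicates, grid, reference_peaks,
                             config = peak_pick_config(), ci_mult = 1.96) {
  if (is.list(replicates) && !is.matrix(replicates)) {
    replicates <- do.call(cbind, replicates)
  }
  if (is.null(dim(replicates)) || ncol(replicates) == 0L) {
    stop("need at least one replicate profile", call. = FALSE)
  }
  B <- ncol(replicates)
  rep_peaks <- lapply(seq_len(B), function(b) {
    find_peaks(replicates[, b], config, x = grid)$location
  })
  w <- config$reliability_window * window_scale(config, grid)
  rows <- lapply(seq_len(nrow(reference_peaks)), function(k) {
    loc <- reference_peaks$location[k]
    matched <- vapply(rep_peaks, function(pp) {
      if (length(pp) == 0L) return(NA_real_)
      d <- abs(pp - loc)
      if (min(d) <= w) pp[which.min(d)] else NA_real_
    }, numeric(1))
    rel <- mean(!is.na(matched))
    m <- matched[!is.na(matched)]
    mu <- if (length(m)) mean(m) else NA_real_
    sdv <- if (length(m) > 1L) stats::sd(m) else 0
    data.frame(location = loc, height = reference_peaks$height[k],
               reliability = rel,
               ci_low = mu - ci_mult * sdv, ci_high = mu + ci_mult * sdv)
  })
  out <- do.call(rbind, rows)
  out <- out[out$reliability > config$reliability_threshold, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peak_set", "data.frame")
  out
}
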