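#' Z-score ratings within participants
#'
#' Centers and scales each participant's ratings to mean 0 and (sample)
#' standard deviation 1, removing between-participant differences in scale
#' usage. Participants with a single rating or constant ratings get z = 0.
#'
#' @param data Data frame with columns `participant` and `rating` (plus any
#'   stimulus coordinate columns, which are passed through untouched).
#' @param value Name of the rating column (default `"rating"`).
#' @return The same data frame with the rating column replaced by z-scores.
#' @export
zscore_within_participant <- function(data, value = "rating") {
  if (nrow(data) == 0L) stop("empty rating dataset", call. = FALSE)
  stopifnot("participant" %in% names(data), value %in% names(data))
  y <- data[[value]]
  grp <- as.factor(data$participant)
  mu <- stats::ave(y, grp, FUN = mean)
  sdv <- stats::ave(y, grp, FUN = function(v) {
    if (length(v) < 2L) return(0)
    stats::sd(v)
  })
  z <- ifelse(sdv > 0, (y - mu) / sdv, 0)
  data[[value]] <- z
  data
}

# Gaussian product-kernel weight matrix: grid rows x data rows.
# grid: data.frame/matrix with one column per coordinate; bandwidth: one sd
# per coordinate.
kernel_weights <- function(grid, data, coords, bandwidth) {
  grid <- as.matrix(grid)
  if (length(bandwidth) == 1L) bandwidth <- rep(bandwidth, length(coords))
  stopifnot(length(bandwidth) == length(coords), all(bandwidth > 0))
  W <- matrix(1, nrow = nrow(grid), ncol = nrow(data))
  for (j in seq_along(coords)) {
    d <- outer(grid[, j], data[[coords[j]]], `-`)
    W <- W * exp(-d^2 / (2 * bandwidth[j]^2))
  }
  W
}

as_grid_df <- function(grid, coords) {
  if (is.null(dim(grid))) {
    g <- data.frame(grid)
    names(g) <- coords[1]
    g
  } else as.data.frame(grid)
}

#' Kernel-smoothed consonance profile
#'
#' Nadaraya-Watson estimate: at each grid point the profile value is the
#' weighted mean of the ratings, with Gaussian weights (standard deviation
#' `bandwidth`) on the distance between the grid point and each trial's
#' stimulus coordinates. With two coordinates (e.g. interval x roll-off) a
#' product kernel is used with one bandwidth per dimension. Weights are
#' untruncated and no boundary correction is applied. Grid points whose
#' total kernel weight falls below `1e-12` get `NA` (flagged, not silently
#' zero).
#'
#' @param data Data frame of (z-scored) trial ratings.
#' @param grid Numeric vector (1D) or data frame/matrix (one column per
#'   coordinate) of evaluation points.
#' @param bandwidth Kernel standard deviation(s); conventionally 0.2
#'   semitones for 15-semitone interval ranges, 0.035 for 0.5-semitone
#'   tuning windows, and 1.5 dB/octave on a roll-off dimension.
#' @param coords Names of the coordinate columns (default `"interval"`).
#' @param value Name of the rating column.
#' @return An object of class `consonance_profile`: a data frame with the
#'   grid coordinates and a `value` column.
#' @export
smooth_profile <- function(data, grid, bandwidth = 0.2,
                           coords = "interval", value = "rating") {
  if (nrow(data) == 0L) stop("empty rating dataset", call. = FALSE)
  gdf <- as_grid_df(grid, coords)
  W <- kernel_weights(gdf, data, coords, bandwidth)
  tot <- rowSums(W)
  val <- as.vector(W %*% data[[value]]) / tot
  val[tot < 1e-12] <- NA_real_
  out <- cbind(gdf, value = val)
  class(out) <- c("consonance_profile", "data.frame")
  out
}

# per-participant kernel numerators/denominators; the sufficient statistics
# for any participant-level resampling of the smoothed profile
participant_stats <- function(data, grid, bandwidth, coords, value) {
  gdf <- as_grid_df(grid, coords)
  participants <- unique(data$participant)
  num <- matrix(0, nrow = nrow(gdf), ncol = length(participants))
  den <- matrix(0, nrow = nrow(gdf), ncol = length(participants))
  for (j in seq_along(participants)) {
    rows <- data[data$participant == participants[j], , drop = FALSE]
    W <- kernel_weights(gdf, rows, coords, bandwidth)
    num[, j] <- W %*% rows[[value]]
    den[, j] <- rowSums(W)
  }
  list(grid = gdf, num = num, den = den, participants = participants)
}

profile_from_stats <- function(stats, idx) {
  num <- rowSums(stats$num[, idx, drop = FALSE])
  den <- rowSums(stats$den[, idx, drop = FALSE])
  val <- num / den
  val[den < 1e-12] <- NA_real_
  val
}

#' Bootstrap confidence bands for a smoothed profile
#'
#' Nonparametric bootstrap over participants: participants are resampled
#' with replacement `n_boot` times, the smoothed profile is recomputed for
#' each replicate, the pointwise standard deviation over replicates gives
#' the standard error, and confidence bands are the Gaussian approximation
#' `mean +/- ci_mult * se`. Deterministic given `seed`.
#'
#' @inheritParams smooth_profile
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param ci_mult Half-width multiplier (default 1.96 for 95% bands).
#' @param seed Integer seed.
#' @param keep_replicates Keep the grid x `n_boot` matrix of replicate
#'   profiles as attribute `"replicates"` (needed for peak reliability).
#' @return A `consonance_profile` with columns `value`, `se`, `ci_low`,
#'   `ci_high`.
#' @export
bootstrap_profile <- function(data, grid, bandwidth = 0.2,
                              coords = "interval", value = "rating",
                              n_boot = 1000, ci_mult = 1.96, seed = 1,
                              keep_replicates = FALSE) {
  st <- participant_stats(data, grid, bandwidth, coords, value)
  P <- length(st$participants)
  if (P < 2L) stop("need at least 2 participants to bootstrap", call. = FALSE)
  mean_val <- profile_from_stats(st, seq_len(P))
  reps <- local_rng(seed, {
    vapply(seq_len(n_boot), function(b) {
      profile_from_stats(st, sample.int(P, P, replace = TRUE))
    }, numeric(nrow(st$grid)))
  })
  se <- apply(reps, 1, stats::sd)
  out <- cbind(st$grid, value = mean_val, se = se,
               ci_low = mean_val - ci_mult * se,
               ci_high = mean_val + ci_mult * se)
  class(out) <- c("consonance_profile", "data.frame")
  if (keep_replicates) attr(out, "replicates") <- reps
  out
}

#' Smoothed model consonance profile
#'
#' Evaluates a model score function on the grid and applies the same
#' Gaussian smoothing as used for behavioral profiles, maximizing
#' comparability between model and behavioral curves. Passing a very small
#' bandwidth approaches the raw model values.
#'
#' @param model A function mapping a numeric vector of grid coordinates to
#'   model scores, or a numeric vector of precomputed scores at `grid`.
#' @param grid Numeric vector of evaluation points (1D).
#' @param bandwidth Kernel standard deviation.
#' @return A `consonance_profile` data frame.
#' @export
model_profile <- function(model, grid, bandwidth = 0.2) {
  vals <- if (is.function(model)) model(grid) else model
  stopifnot(length(vals) == length(grid))
  df <- data.frame(interval = grid, rating = vals)
  smooth_profile(df, grid, bandwidth, coords = "interval", value = "rating")
}

#' Monte Carlo split-half reliability of a smoothed profile
#'
#' Randomly splits participants into halves `n_perm` times, smooths each
#' half's ratings separately, and correlates the two profiles. High mean
#' correlations indicate that the sample size supports the chosen
#' bandwidth.
#'
#' @inheritParams bootstrap_profile
#' @param n_perm Number of random splits (default 1000).
#' @return List with `r` (mean Pearson correlation), `ci` (2.5 and 97.5
#'   percentiles over splits), and `r_values`.
#' @export
split_half_reliability <- function(data, grid, bandwidth = 0.2,
                                   coords = "interval", value = "rating",
                                   n_perm = 1000, seed = 1) {
  st <- participant_stats(data, grid, bandwidth, coords, value)
  P <- length(st$participants)
  if (P < 4L) stop("need at least 4 participants", call. = FALSE)
  rs <- local_rng(seed, {
    vapply(seq_len(n_perm), function(b) {
      half <- sample.int(P, floor(P / 2))
      v1 <- profile_from_stats(st, half)
      v2 <- profile_from_stats(st, setdiff(seq_len(P), half))
      ok <- is.finite(v1) & is.finite(v2)
      if (sum(ok) < 3 || stats::sd(v1[ok]) == 0 || stats::sd(v2[ok]) == 0) {
        return(NA_real_)
      }
      stats::cor(v1[ok], v2[ok])
    }, numeric(1))
  })
  list(r = mean(rs, na.rm = TRUE),
       ci = stats::quantile(rs, c(0.025, 0.975), na.rm = TRUE, names = FALSE),
       r_values = rs)
}

# run expr with a temporary RNG state seeded by `seed`, restoring the
# caller's RNG afterwards
local_rng <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
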