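#' Configuration for Gibbs-Sampling-with-People simulation
#'
#' Chains of simulated raters explore a 2D triad space (two stacked
#' intervals above a bass). Each iteration, the active responder replaces
#' one coordinate with their preferred value along a slider while the other
#' is held fixed; the active dimension alternates between iterations, so
#' the chain performs coordinate-wise (Gibbs-style) optimization of the
#' utility surface.
#'
#' @param dim_ranges List of two length-2 ranges in semitones (default
#'   `[0.5, 8.5]` on both interval dimensions).
#' @param n_chains Number of chains (default 200).
#' @param chain_length Iterations per chain, excluding the random start
#'   (default 40).
#' @param slider_grid Candidate slider positions per sweep (default 400).
#' @param responder `"argmax"` (deterministic utility maximization; ties
#'   break to the first/lowest candidate) or `"softmax"` (sample with
#'   probability proportional to `exp(utility / tau)`).
#' @param tau Softmax temperature in utility units (default 0.05).
#' @param kde_bandwidth Kernel density bandwidth for aggregating human
#'   (simulated) iterations, semitones (default 0.375).
#' @param model_kde_bandwidth Bandwidth for smoothing model utility
#'   surfaces (default 0.1875).
#' @param out_grid Output density grid size per dimension (default 500).
#' @param seed Integer seed.
#' @return An object of class `gsp_config`.
#' @export
gsp_config <- function(dim_ranges = list(c(0.5, 8.5), c(0.5, 8.5)),
                       n_chains = 200, chain_length = 40, slider_grid = 400,
                       responder = c("argmax", "softmax"), tau = 0.05,
                       kde_bandwidth = 0.375, model_kde_bandwidth = 0.1875,
                       out_grid = 500, seed = 1) {
  responder <- match.arg(responder)
  stopifnot(length(dim_ranges) == 2L, chain_length >= 1,
            kde_bandwidth > 0, model_kde_bandwidth > 0, slider_grid >= 2)
  for (rg in dim_ranges) stopifnot(length(rg) == 2L, rg[1] < rg[2])
  structure(list(dim_ranges = dim_ranges, n_chains = n_chains,
                 chain_length = chain_length, slider_grid = slider_grid,
                 responder = responder, tau = tau,
                 kde_bandwidth = kde_bandwidth,
                 model_kde_bandwidth = model_kde_bandwidth,
                 out_grid = out_grid, seed = seed),
            class = "gsp_config")
}

#' Simulate GSP chains over a 2D utility surface
#'
#' Each chain starts at a uniform random point in the domain. At each
#' iteration, the active coordinate is replaced by the responder's choice
#' among `slider_grid` equally spaced candidate values (the other
#' coordinate fixed): the utility argmax, or a softmax sample at
#' temperature `tau`. Active dimensions alternate, starting from a randomly
#' chosen dimension per chain. Deterministic given `config$seed`.
#'
#' @param utility Function `(i1, i2) -> utility`, vectorized over its
#'   arguments and finite on the domain.
#' @param config A [gsp_config()].
#' @return Data frame of class `gsp_chains` with columns `chain`,
#'   `iteration` (0 is the random start), `active_dim` (NA at the start),
#'   `i1`, `i2`.
#' @export
run_gsp_chains <- function(utility, config = gsp_config()) {
  r1 <- config$dim_ranges[[1]]; r2 <- config$dim_ranges[[2]]
  cand <- list(seq(r1[1], r1[2], length.out = config$slider_grid),
               seq(r2[1], r2[2], length.out = config$slider_grid))
  out <- local_rng(config$seed, {
    rows <- vector("list", config$n_chains)
    for (ch in seq_len(config$n_chains)) {
      pt <- c(stats::runif(1, r1[1], r1[2]), stats::runif(1, r2[1], r2[2]))
      first_dim <- sample(1:2, 1)
      i1 <- numeric(config$chain_length + 1L)
      i2 <- numeric(config$chain_length + 1L)
      dims <- integer(config$chain_length + 1L)
      i1[1] <- pt[1]; i2[1] <- pt[2]; dims[1] <- NA_integer_
      for (it in seq_len(config$chain_length)) {
        dim_k <- if ((it + first_dim) %% 2 == 0) 1L else 2L
        cc <- cand[[dim_k]]
        u <- if (dim_k == 1L) utility(cc, rep(pt[2], length(cc)))
             else utility(rep(pt[1], length(cc)), cc)
        if (any(!is.finite(u))) {
          bad <- which(!is.finite(u))[1]
          stop(sprintf("non-finite utility at (%.4g, %.4g)",
                       if (dim_k == 1L) cc[bad] else pt[1],
                       if (dim_k == 1L) pt[2] else cc[bad]), call. = FALSE)
        }
        choice <- if (config$responder == "argmax") {
          cc[which.max(u)]
        } else {
          pr <- exp((u - max(u)) / config$tau)
          cc[sample.int(length(cc), 1, prob = pr)]
        }
        pt[dim_k] <- choice
        i1[it + 1L] <- pt[1]; i2[it + 1L] <- pt[2]; dims[it + 1L] <- dim_k
      }
      rows[[ch]] <- data.frame(chain = ch,
                               iteration = 0:config$chain_length,
                               active_dim = dims, i1 = i1, i2 = i2)
    }
    do.call(rbind, rows)
  })
  class(out) <- c("gsp_chains", "data.frame")
  out
}

#' Aggregate GSP iterations with a 2D kernel density estimate
#'
#' Pools all chain iterations (excluding the random starting points) and
#' evaluates an isotropic Gaussian KDE on a regular grid over the domain.
#' The raw density integrates to ~1 over the plane; a unit-interval
#' rescaled copy (min -> 0, max -> 1) is also returned for plotting.
#'
#' @param chains A `gsp_chains` data frame (or any data frame with `i1`,
#'   `i2` columns; rows with `iteration == 0` are dropped when present).
#' @param config A [gsp_config()]; uses `kde_bandwidth` and `out_grid`.
#' @return List of class `gsp_density` with `x`, `y` (grid coordinates),
#'   `density` (matrix, x by y), and `scaled` (unit-interval rescale).
#' @export
aggregate_gsp_kde <- function(chains, config = gsp_config()) {
  if ("iteration" %in% names(chains)) {
    chains <- chains[chains$iteration > 0, , drop = FALSE]
  }
  if (nrow(chains) == 0L) stop("no chain iterations to aggregate", call. = FALSE)
  r1 <- config$dim_ranges[[1]]; r2 <- config$dim_ranges[[2]]
  gx <- seq(r1[1], r1[2], length.out = config$out_grid)
  gy <- seq(r2[1], r2[2], length.out = config$out_grid)
  h <- config$kde_bandwidth
  n <- nrow(chains)
  Kx <- exp(-outer(gx, chains$i1, `-`)^2 / (2 * h^2))
  Ky <- exp(-outer(gy, chains$i2, `-`)^2 / (2 * h^2))
  dens <- (Kx %*% t(Ky)) / (n * 2 * pi * h^2)
  rng <- range(dens)
  scaled <- if (diff(rng) > 0) (dens - rng[1]) / diff(rng) else dens * 0
  structure(list(x = gx, y = gy, density = dens, scaled = scaled),
            class = "gsp_density")
}

#' Location of the octave diagonal in a GSP density
#'
#' Chords whose two intervals sum to an octave-like total form an
#' anti-diagonal ridge in the triad plane. This projects the density onto
#' the summed-interval coordinate `s = i1 + i2`, restricts to a band around
#' the octave, and returns a mass-weighted location estimate of the ridge:
#' the projected maximum refined by the weighted mean of `s` within one KDE
#' bandwidth of it.
#'
#' @param density A `gsp_density` from [aggregate_gsp_kde()].
#' @param band Length-2 range of `s` to search (default `c(10.5, 13.5)`).
#' @param bin_width Projection bin width in semitones (default 0.02).
#' @param refine_halfwidth Half-width of the mass-weighted refinement
#'   around the projected maximum (default 0.375).
#' @return Diagonal location in semitones (`i1 + i2`).
#' @export
octave_diagonal_location <- function(density, band = c(10.5, 13.5),
                                     bin_width = 0.02,
                                     refine_halfwidth = 0.375) {
  stopifnot(inherits(density, "gsp_density"))
  dr <- range(density$density)
  if (diff(dr) <= 1e-8 * max(dr)) {
    stop("density is uniform; no distinguished diagonal band", call. = FALSE)
  }
  s <- outer(density$x, density$y, `+`)
  d <- as.vector(density$density)
  sv <- as.vector(s)
  breaks <- seq(min(sv), max(sv) + bin_width, by = bin_width)
  bin <- findInterval(sv, breaks)
  mass <- tapply(d, bin, sum)
  centers <- breaks[as.integer(names(mass))] + bin_width / 2
  in_band <- centers >= band[1] & centers <= band[2]
  if (!any(in_band)) stop("no projected mass in the requested band", call. = FALSE)
  mass_b <- as.numeric(mass[in_band]); centers_b <- centers[in_band]
  s_max <- centers_b[which.max(mass_b)]
  near <- abs(centers_b - s_max) <= refine_halfwidth
  sum(centers_b[near] * mass_b[near]) / sum(mass_b[near])
}

#' Precompute a fast interpolated 2D utility
#'
#' Evaluates an expensive model utility on an `n x n` grid once and returns
#' a bilinear interpolant, making GSP simulation over model surfaces cheap.
#' Points outside the grid are clamped to its edge.
#'
#' @param fun Function `(i1, i2) -> score`, vectorized.
#' @param ranges List of two length-2 ranges.
#' @param n Grid resolution per dimension (default 101).
#' @return A vectorized function `(i1, i2) -> utility`.
#' @export
grid_utility <- function(fun, ranges = list(c(0.5, 8.5), c(0.5, 8.5)),
                         n = 101) {
  gx <- seq(ranges[[1]][1], ranges[[1]][2], length.out = n)
  gy <- seq(ranges[[2]][1], ranges[[2]][2], length.out = n)
  pts <- expand.grid(i1 = gx, i2 = gy)
  z <- matrix(fun(pts$i1, pts$i2), nrow = n, ncol = n)
  dx <- gx[2] - gx[1]; dy <- gy[2] - gy[1]
  function(i1, i2) {
    x <- pmin(pmax(i1, gx[1]), gx[n])
    y <- pmin(pmax(i2, gy[1]), gy[n])
    ix <- pmin(pmax(floor((x - gx[1]) / dx) + 1L, 1L), n - 1L)
    iy <- pmin(pmax(floor((y - gy[1]) / dy) + 1L, 1L), n - 1L)
    tx <- (x - gx[ix]) / dx
    ty <- (y - gy[iy]) / dy
    z[cbind(ix, iy)] * (1 - tx) * (1 - ty) +
      z[cbind(ix + 1L, iy)] * tx * (1 - ty) +
      z[cbind(ix, iy + 1L)] * (1 - tx) * ty +
      z[cbind(ix + 1L, iy + 1L)] * tx * ty
  }
}

#' Composite-model utility over the triad plane
#'
#' Convenience builder: the median-normalized composite consonance of the
#' triad `(bass, bass + i1, bass + i1 + i2)` as a vectorized function of
#' the two intervals, precomputed on a grid via [grid_utility()].
#'
#' @param timbres A [timbre()] or list of three timbres.
#' @param bass Bass pitch (MIDI, default 60).
#' @param params A [composite_params()].
#' @param ranges Interval ranges (default `[0.5, 8.5]^2`).
#' @param n Precomputation grid resolution (default 101).
#' @return A vectorized utility function `(i1, i2) -> score`.
#' @export
composite_triad_utility <- function(timbres = timbre("harmonic"), bass = 60,
                                    params = composite_params(),
                                    ranges = list(c(0.5, 8.5), c(0.5, 8.5)),
                                    n = 101) {
  raw_fun <- function(i1, i2) {
    score_profile("composite", cbind(i1, i2), bass = bass,
                  timbres = timbres, params = params)
  }
  f <- grid_utility(raw_fun, ranges, n)
  # median-normalize over the precomputed grid
  gx <- seq(ranges[[1]][1], ranges[[1]][2], length.out = n)
  gy <- seq(ranges[[2]][1], ranges[[2]][2], length.out = n)
  pts <- expand.grid(i1 = gx, i2 = gy)
  med <- stats::median(f(pts$i1, pts$i2))
  function(i1, i2) f(i1, i2) - med
}
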