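#' Jaccard similarity between two sets of peak locations
#'
#' Peaks are matched one-to-one greedily by increasing pairwise distance;
#' a pair counts as overlapping when separated by less than `tol`. With `m`
#' matches, the similarity is `m / (|A| + |B| - m)`. Two empty sets agree
#' perfectly (`J = 1`); an empty set versus a nonempty one gives 0.
#'
#' @param peaks_a,peaks_b Numeric vectors of peak locations (semitones).
#' @param tol Overlap tolerance in the same units (> 0); conventionally
#'   2.67% of the profile's interval range (0.4 semitones on a 15-semitone
#'   range).
#' @return Similarity in `[0, 1]`.
#' @export
#' @examples
#' peak_jaccard(c(3, 7, 12), c(3.1, 7.2, 12.05), tol = 0.4) # 1
#' peak_jaccard(c(3, 7), c(7, 12), tol = 0.4)               # 1/3
peak_jaccard <- function(peaks_a, peaks_b, tol) {
  if (tol <= 0) stop("'tol' must be > 0", call. = FALSE)
  na <- length(peaks_a); nb <- length(peaks_b)
  if (na == 0L && nb == 0L) return(1)
  if (na == 0L || nb == 0L) return(0)
  d <- abs(outer(peaks_a, peaks_b, `-`))
  pairs <- which(d < tol, arr.ind = TRUE)
  if (nrow(pairs)) pairs <- pairs[order(d[pairs]), , drop = FALSE]
  used_a <- logical(na); used_b <- logical(nb); m <- 0L
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- TRUE; used_b[j] <- TRUE; m <- m + 1L
    }
  }
  m / (na + nb - m)
}

#' Define a dyad experiment for model fitting
#'
#' Bundles the ingredients the fit objective needs for one experiment: the
#' (bootstrap-filtered) behavioral peak locations, the stimulus timbres,
#' and the interval range.
#'
#' @param behavioral_peaks Numeric vector of reliable behavioral peak
#'   locations (semitones).
#' @param timbres A [timbre()] or list of timbres for the chord tones.
#' @param range Interval range, length-2 numeric (e.g. `c(0, 15)`).
#' @param bass Bass pitch (MIDI).
#' @param n_grid Profile grid size (default 1000).
#' @param bandwidth Smoothing bandwidth for the model profile; defaults to
#'   0.2 semitones scaled by `range / 15`.
#' @return A list of class `fit_experiment`.
#' @export
fit_experiment <- function(behavioral_peaks, timbres, range = c(0, 15),
                           bass = 60, n_grid = 1000,
                           bandwidth = 0.2 * diff(range) / 15) {
  stopifnot(length(range) == 2L, range[1] < range[2])
  structure(list(behavioral_peaks = behavioral_peaks, timbres = timbres,
                 range = range, bass = bass, n_grid = n_grid,
                 bandwidth = bandwidth),
            class = "fit_experiment")
}

#' Peak-Jaccard model-fit objective
#'
#' For each experiment, computes the composite-model consonance profile
#' under the candidate parameters, smooths it like a behavioral profile,
#' detects model peaks (with the stricter sharpness threshold `beta = 0.05`
#' standing in for bootstrap filtering, since model output is
#' deterministic), and measures the Jaccard similarity to the behavioral
#' peaks with tolerance `overlap_frac` of the interval range. The overall
#' fit is the mean similarity across experiments.
#'
#' @param params Named list or vector with elements `p`, `q`, `r` (revised
#'   interference kernel) and `w_h` (harmonicity weight).
#' @param experiments List of [fit_experiment()] objects.
#' @param overlap_frac Overlap tolerance as a fraction of the interval
#'   range (default 0.0267, i.e. 0.4 semitones on 15 semitones).
#' @param peak_config Peak-picking configuration for model profiles
#'   (default `peak_pick_config(beta = 0.05)`).
#' @return Mean Jaccard similarity in `[0, 1]`.
#' @export
fit_objective <- function(params, experiments, overlap_frac = 0.0267,
                          peak_config = peak_pick_config(beta = 0.05)) {
  if (length(experiments) == 0L) stop("no experiments supplied", call. = FALSE)
  params <- as.list(params)
  cp <- composite_params(
    w_harmonicity = params$w_h,
    dissonance = dissonance_params(p = params$p, q = params$q, r = params$r))
  sims <- vapply(experiments, function(ex) {
    grid <- seq(ex$range[1], ex$range[2], length.out = ex$n_grid)
    raw <- score_profile("composite", grid, bass = ex$bass,
                         timbres = ex$timbres, params = cp)
    prof <- model_profile(normalize_profile(raw), grid, ex$bandwidth)
    model_peaks <- find_peaks(prof, peak_config)$location
    peak_jaccard(ex$behavioral_peaks, model_peaks,
                 tol = overlap_frac * diff(ex$range))
  }, numeric(1))
  mean(sims)
}

# map unconstrained optimizer coordinates to a box via logistic transform
to_box <- function(theta, lower, upper) {
  lower + (upper - lower) / (1 + exp(-theta))
}
from_box <- function(x, lower, upper) {
  z <- pmin(pmax((x - lower) / (upper - lower), 1e-6), 1 - 1e-6)
  log(z / (1 - z))
}

#' Gradient-free maximization of a fit objective
#'
#' Box-constrained Nelder-Mead maximization with randomized restarts, a
#' simple stand-in for subplex-style derivative-free optimization. The
#' parameter box is handled by a logistic reparameterization. Starts are
#' the supplied `start` plus `n_restarts - 1` perturbations drawn uniformly
#' within the box; deterministic given `seed`. Because peak-based
#' objectives are piecewise constant, the best evaluated point (including
#' the starts) is returned.
#'
#' @param objective Function mapping a named parameter list to a scalar to
#'   maximize; non-finite values abort with the offending parameters.
#' @param start Named numeric vector of starting values.
#' @param lower,upper Named bounds (same names as `start`).
#' @param max_eval Budget of objective evaluations per start.
#' @param n_restarts Number of starts (default 3).
#' @param seed Integer seed for the restart draws.
#' @return List with `par` (best parameters), `value`, `evaluations`, and
#'   `trace` (data frame of best-so-far objective values).
#' @export
optimize_params <- function(objective, start, lower, upper,
                            max_eval = 200, n_restarts = 3, seed = 1) {
  stopifnot(all(names(start) == names(lower)),
            all(names(start) == names(upper)), all(lower < upper))
  n_eval <- 0L
  best <- list(par = start, value = -Inf)
  trace <- list()
  eval_at <- function(x) {
    val <- objective(as.list(x))
    if (!is.finite(val)) {
      stop("objective returned a non-finite value at: ",
           paste(sprintf("%s=%.4g", names(x), x), collapse = ", "),
           call. = FALSE)
    }
    n_eval <<- n_eval + 1L
    if (val > best$value) best <<- list(par = x, value = val)
    trace[[length(trace) + 1L]] <<- c(eval = n_eval, best = best$value)
    val
  }
  starts <- list(start)
  if (n_restarts > 1L) {
    extra <- local_rng(seed, {
      lapply(seq_len(n_restarts - 1L), function(i) {
        s <- lower + stats::runif(length(lower)) * (upper - lower)
        names(s) <- names(start)
        s
      })
    })
    starts <- c(starts, extra)
  }
  for (s in starts) {
    theta0 <- from_box(s, lower, upper)
    suppressWarnings(stats::optim(
      theta0,
      function(theta) -eval_at(to_box(theta, lower, upper)),
      method = "Nelder-Mead",
      control = list(maxit = max_eval)))
  }
  trace <- as.data.frame(do.call(rbind, trace))
  list(par = best$par, value = best$value, evaluations = n_eval,
       trace = trace)
}
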