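make_ratings <- function(participants, intervals, ratings) {
  data.frame(participant = participants, interval = intervals,
             bass = 60, rating = ratings)
}

test_that("zscore_within_participant uses the sample-sd convention", {
  d <- make_ratings(c(1, 1), c(2, 10), c(1, 7))
  z <- zscore_within_participant(d)
  expect_equal(z$rating, c(-0.70710678, 0.70710678), tolerance = 1e-8)

  # constant raters and single-trial raters get zeros
  d2 <- make_ratings(c(1, 1, 2), c(1, 2, 3), c(4, 4, 6))
  expect_equal(zscore_within_participant(d2)$rating, c(0, 0, 0))

  # idempotent on already-z-scored data
  set.seed(3)
  d3 <- make_ratings(rep(1:5, each = 20), runif(100, 0, 15),
                     rnorm(100))
  once <- zscore_within_participant(d3)
  twice <- zscore_within_participant(once)
  expect_equal(twice$rating, once$rating, tolerance = 1e-12)
  expect_error(zscore_within_participant(d3[0, ]), "empty")
})

test_that("smooth_profile is a Nadaraya-Watson estimator", {
  set.seed(11)
  d <- make_ratings(rep(1:4, each = 50), runif(200, 0, 15), rnorm(200))
  grid <- seq(0, 15, length.out = 40)
  prof <- smooth_profile(d, grid, bandwidth = 0.4)
  # brute-force oracle at 10 grid points
  for (k in seq(1, 40, by = 4)) {
    expect_equal(prof$value[k],
                 nw_oracle(grid[k], d$interval, d$rating, 0.4),
                 tolerance = 1e-12)
  }
  # constant ratings give a constant profile
  dc <- make_ratings(1:10, runif(10, 0, 15), rep(3, 10))
  expect_equal(smooth_profile(dc, grid, bandwidth = 3)$value, rep(3, 40))
  # a single rating dominates everywhere (weights cancel)
  d1 <- make_ratings(1, 7.3, 5)
  expect_equal(smooth_profile(d1, grid, bandwidth = 5)$value, rep(5, 40))
  # linear signal is recovered up to O(bandwidth^2) in the interior
  dl <- make_ratings(rep(1, 2000), seq(0, 15, length.out = 2000),
                     seq(0, 15, length.out = 2000))
  pl <- smooth_profile(dl, grid, bandwidth = 0.2)
  interior <- grid > 1 & grid < 14
  expect_lt(max(abs(pl$value[interior] - grid[interior])), 0.05)
  # unreachable grid points are flagged NA, not zero
  far <- smooth_profile(d1, c(7, 500), bandwidth = 0.2)
  expect_true(is.na(far$value[2]) && !is.na(far$value[1]))
})

test_that("smoothing is linear in ratings and invariant to row order", {
  set.seed(12)
  d <- make_ratings(rep(1:3, each = 30), runif(90, 0, 15), rnorm(90))
  grid <- seq(0, 15, length.out = 25)
  p1 <- smooth_profile(d, grid)
  shuffled <- d[sample(nrow(d)), ]
  expect_equal(smooth_profile(shuffled, grid)$value, p1$value)
  d2 <- d; d2$rating <- 2 * d$rating + 1
  expect_equal(smooth_profile(d2, grid)$value, 2 * p1$value + 1,
               tolerance = 1e-12)
})

test_that("2D smoothing uses a product kernel over interval and roll-off", {
  set.seed(13)
  n <- 300
  d <- data.frame(participant = rep(1:10, each = 30),
                  interval = runif(n, 0, 15), rolloff = runif(n, 0, 15),
                  rating = rnorm(n))
  grid <- expand.grid(interval = seq(1, 14, length.out = 8),
                      rolloff = c(2, 7, 12))
  prof <- smooth_profile(d, grid, bandwidth = c(0.5, 1.5),
                         coords = c("interval", "rolloff"))
  # product-kernel oracle at a few points
  for (k in c(1, 10, 24)) {
    w <- exp(-(d$interval - grid$interval[k])^2 / (2 * 0.5^2)) *
      exp(-(d$rolloff - grid$rolloff[k])^2 / (2 * 1.5^2))
    expect_equal(prof$value[k], sum(w * d$rating) / sum(w), tolerance = 1e-12)
  }
})

test_that("bootstrap_profile quantifies participant-level uncertainty", {
  grid <- seq(0, 15, length.out = 30)
  # identical participants: zero-width intervals
  base <- data.frame(interval = seq(0.5, 14.5, length.out = 20),
                     rating = sin(seq(0.5, 14.5, length.out = 20)))
  d_same <- do.call(rbind, lapply(1:6, function(p) {
    cbind(participant = p, base, bass = 60)
  }))
  bp <- bootstrap_profile(d_same, grid, bandwidth = 0.5, n_boot = 50, seed = 4)
  expect_lt(max(bp$se), 1e-12)
  expect_equal(bp$ci_low, bp$value, tolerance = 1e-9)

  # determinism under a fixed seed
  set.seed(99)
  d <- make_ratings(rep(1:8, each = 25), runif(200, 0, 15), rnorm(200))
  b1 <- bootstrap_profile(d, grid, n_boot = 40, seed = 7)
  b2 <- bootstrap_profile(d, grid, n_boot = 40, seed = 7)
  expect_identical(b1$se, b2$se)
  expect_error(bootstrap_profile(d[d$participant == 1, ], grid), "2 participants")
})

test_that("bootstrap CI width shrinks like one over root N", {
  grid <- seq(2, 13, length.out = 15)
  widths <- vapply(c(25, 100, 400), function(P) {
    set.seed(P)
    d <- make_ratings(rep(seq_len(P), each = 10), runif(P * 10, 0, 15),
                      rnorm(P * 10))
    bp <- bootstrap_profile(d, grid, bandwidth = 1.0, n_boot = 60, seed = 5)
    mean(bp$ci_high - bp$ci_low)
  }, numeric(1))
  slope <- coef(lm(log(widths) ~ log(c(25, 100, 400))))[2]
  expect_gt(slope, -0.7)
  expect_lt(slope, -0.3)
})

test_that("model_profile smooths model outputs like behavioral data", {
  grid <- seq(0, 15, length.out = 200)
  expect_equal(model_profile(rep(2, 200), grid)$value, rep(2, 200))
  # near-delta bandwidth returns roughly the raw values
  vals <- sin(grid)
  mp <- model_profile(vals, grid, bandwidth = 0.001)
  expect_equal(mp$value, vals, tolerance = 1e-6)
  # a broad isolated maximum stays put to within half a bandwidth
  bump <- exp(-(grid - 6.2)^2 / (2 * 1.5^2))
  mp2 <- model_profile(bump, grid, bandwidth = 0.2)
  expect_lt(abs(grid[which.max(mp2$value)] - 6.2), 0.1)
})

test_that("split-half reliability separates signal from noise", {
  grid <- seq(0, 15, length.out = 30)
  # deterministic raters reading the same surface: r ~ 1
  surface <- function(x) sin(x)
  d_clean <- do.call(rbind, lapply(1:12, function(p) {
    x <- seq(0.2, 14.8, length.out = 25)
    make_ratings(rep(p, 25), x, surface(x))
  }))
  sh <- split_half_reliability(d_clean, grid, bandwidth = 0.5,
                               n_perm = 20, seed = 2)
  expect_gt(sh$r, 0.999)
  # pure noise: r distribution centered near zero
  set.seed(21)
  d_noise <- make_ratings(rep(1:40, each = 20), runif(800, 0, 15), rnorm(800))
  shn <- split_half_reliability(d_noise, grid, bandwidth = 0.5,
                                n_perm = 60, seed = 2)
  expect_lt(abs(shn$r), 0.35)
  # deterministic under a fixed seed
  shn2 <- split_half_reliability(d_noise, grid, bandwidth = 0.5,
                                 n_perm = 60, seed = 2)
  expect_identical(shn$r_values, shn2$r_values)
  expect_error(split_half_reliability(d_clean[d_clean$participant < 3, ],
                                      grid), "4 participants")
})

test_that("simulated raters reproduce the generating model profile", {
  grid <- seq(0, 15, length.out = 300)
  surf <- composite_surface(harmonic_timbre, n_grid = 300)
  d <- simulate_dense_ratings(rater_model(surf, n_participants = 100),
                              seed = 31)
  prof <- smooth_profile(zscore_within_participant(d), grid, 0.2)
  model_sm <- model_profile(surf(grid), grid, 0.2)
  expect_gt(cor(prof$value, model_sm$value), 0.9)
})
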