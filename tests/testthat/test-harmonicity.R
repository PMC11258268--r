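test_that("pc_spectrum deposits circular Gaussians at pitch classes", {
  # a 440 Hz partial sits at pitch class 9 (A)
  sp <- pc_spectrum(tone_spectrum(440, 1))
  peak_bin <- which.max(sp$weights)
  expect_equal((peak_bin - 1) / 100, 9, tolerance = 0.02)

  # octave-equivalent partials pile mass onto one bump
  one <- pc_spectrum(tone_spectrum(440, 1))
  two <- pc_spectrum(tone_spectrum(c(440, 880), c(1, 1)))
  expect_equal(two$weights, 2 * one$weights, tolerance = 1e-9)

  # +1 semitone transposition is a circular shift by resolution/12 bins
  base <- make_tone(timbre("harmonic", n_harmonics = 6, roll_off = 3),
                    midi_to_freq(60))
  up <- tone_spectrum(base$frequency * 2^(1 / 12), base$amplitude)
  w0 <- pc_spectrum(base)$weights
  w1 <- pc_spectrum(up)$weights
  n <- length(w0)
  shifted <- w0[((seq_len(n) - 1 - 100) %% n) + 1]
  expect_equal(w1, shifted, tolerance = 1e-9)

  expect_error(pc_spectrum(NULL), "at least one")
})

test_that("harmonic_template folds harmonics into pitch-class space", {
  t1 <- harmonic_template(1)
  expect_equal(which.max(t1$weights), 1L)
  # two harmonics both fold onto pitch class 0; mass there reflects roll-off
  t2 <- harmonic_template(2, roll_off = 3)
  expect_equal(which.max(t2$weights), 1L)
  expect_equal(max(t2$weights) / max(t1$weights), 1 + 10^(-3 / 20) / 1,
               tolerance = 1e-6)
  # 3rd harmonic lands near pitch class 7.02 (folded perfect twelfth)
  t3 <- harmonic_template(3, roll_off = 0)
  w_upper <- t3$weights
  w_upper[1:300] <- 0; w_upper[900:1200] <- 0
  expect_equal((which.max(w_upper) - 1) / 100, (12 * log2(3)) %% 12,
               tolerance = 0.02)
})

test_that("virtual pitch profile is a circular cosine-similarity sweep", {
  tmpl <- harmonic_template(12, 3)
  # self-similarity at zero shift
  prof <- virtual_pitch_profile(tmpl, tmpl)
  expect_equal(prof$strengths[1], 1, tolerance = 1e-9)
  expect_true(all(prof$strengths >= 0 & prof$strengths <= 1))

  # FFT path agrees with the brute-force loop at reduced resolution
  set.seed(5)
  for (i in 1:3) {
    sp <- random_spectrum(6)
    a <- pc_spectrum(sp, resolution = 120)
    b <- harmonic_template(8, 3, resolution = 120)
    expect_equal(virtual_pitch_profile(a, b, "fft")$strengths,
                 virtual_pitch_profile(a, b, "direct")$strengths,
                 tolerance = 1e-10)
  }

  # transposition equivariance: profile of shifted chord = shifted profile
  base <- make_tone(timbre("harmonic", 6, 3), midi_to_freq(60))
  up <- tone_spectrum(base$frequency * 2^(2 / 12), base$amplitude)
  p0 <- virtual_pitch_profile(pc_spectrum(base), tmpl)$strengths
  p2 <- virtual_pitch_profile(pc_spectrum(up), tmpl)$strengths
  n <- length(p0)
  expect_equal(p2, p0[((seq_len(n) - 1 - 200) %% n) + 1], tolerance = 1e-8)

  mismatched <- harmonic_template(8, 3, resolution = 600)
  expect_error(virtual_pitch_profile(pc_spectrum(base), mismatched), "match")
})

test_that("harmonicity statistics behave on canonical profiles", {
  n <- 100
  uniform <- structure(list(strengths = rep(0.5, n), resolution = n),
                       class = "virtual_pitch_profile")
  expect_equal(harmonicity_hp(uniform), 0)
  onehot <- structure(list(strengths = c(1, rep(0, n - 1)), resolution = n),
                      class = "virtual_pitch_profile")
  expect_equal(harmonicity_hp(onehot), log(n))
  # shift invariance of both statistics
  shifted <- structure(list(strengths = c(rep(0, 10), 1, rep(0, n - 11)),
                            resolution = n),
                       class = "virtual_pitch_profile")
  expect_equal(harmonicity_hp(shifted), harmonicity_hp(onehot))
  expect_equal(harmonicity_milne(shifted), harmonicity_milne(onehot))
  zero <- structure(list(strengths = rep(0, n), resolution = n),
                    class = "virtual_pitch_profile")
  expect_error(harmonicity_hp(zero), "zero")

  # a chord equal to the template maximizes the peak statistic
  tmpl <- harmonic_template(12, 3)
  expect_equal(harmonicity_milne(virtual_pitch_profile(tmpl, tmpl)), 1,
               tolerance = 1e-9)
})

test_that("harmonicity is transposition-invariant through the full pipeline", {
  cp <- composite_params()
  for (shift in c(1, 5, 12)) {
    s0 <- score_profile("hp", 7, bass = 55, params = cp)
    s1 <- score_profile("hp", 7, bass = 55 + shift, params = cp)
    expect_equal(s0, s1, tolerance = 1e-6)
  }
})

test_that("harmonic dyads score higher than detuned ones", {
  cp <- composite_params()
  octave <- score_profile("milne", 12, timbres = harmonic_timbre, params = cp)
  detuned <- score_profile("milne", 12.5, timbres = harmonic_timbre, params = cp)
  expect_gt(octave, detuned)
})

test_that("harmonicity peaks sit at harmonic intervals and resist stretching", {
  grid <- seq(0.5, 15, length.out = 750)
  cfg <- peak_pick_config(beta = 0.05)
  cp <- composite_params()
  h <- score_profile("hp", grid, timbres = harmonic_timbre, params = cp)
  pk <- find_peaks(model_profile(normalize_profile(h), grid, 0.2), cfg)
  for (target in c(5, 7, 12)) {
    expect_true(any(abs(pk$location - target) < 0.15),
                label = sprintf("harmonicity peak near %g", target))
  }
  # stretching the tones does not relocate the peak away from the true
  # octave, and it flattens the profile
  h21 <- score_profile("hp", grid, timbres = stretched_timbre(2.1), params = cp)
  pk21 <- find_peaks(model_profile(normalize_profile(h21), grid, 0.2), cfg)
  expect_true(any(abs(pk21$location - 12) < 0.15))
  expect_lt(sd(h21), 0.75 * sd(h))
})
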