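test_that("midi_to_freq matches its anchors and inverts cleanly", {
  expect_equal(midi_to_freq(69), 440)
  expect_equal(midi_to_freq(81), 880)
  expect_equal(midi_to_freq(60), 261.6255653006, tolerance = 1e-10)
  expect_error(midi_to_freq(NA_real_), "finite")
  expect_error(freq_to_midi(-1), "positive")
  # bijection round trip over the full MIDI range, including fractions
  p <- seq(0, 127, by = 0.37)
  expect_lt(max(abs(freq_to_midi(midi_to_freq(p)) - p)), 1e-9)
  # strictly increasing
  expect_true(all(diff(midi_to_freq(p)) > 0))
})

test_that("make_tone produces the documented spectra for each tone type", {
  t1 <- make_tone(timbre("harmonic", n_harmonics = 10, roll_off = 3), 200)
  expect_equal(nrow(t1), 10)
  expect_equal(t1$frequency, 200 * (1:10))
  expect_equal(t1$amplitude[2], 0.7079458, tolerance = 1e-6)
  expect_equal(t1$amplitude[1], 1)

  t2 <- make_tone(timbre("stretched", gamma = 2.1, roll_off = 3), 200)
  expect_equal(t2$frequency[2], 420)  # gamma^log2(2) = gamma
  expect_equal(t2$amplitude, t1$amplitude)

  # gamma = 2 recovers the harmonic series exactly
  t2h <- make_tone(timbre("stretched", gamma = 2, roll_off = 3), 200)
  expect_equal(t2h$frequency, t1$frequency)

  t3 <- make_tone(timbre("pure"), 440)
  expect_equal(nrow(t3), 1)
  expect_equal(t3$amplitude, 1)

  t4 <- make_tone(timbre("five_equal"), 100)
  expect_equal(t4$frequency, 100 * (1:5))
  expect_equal(t4$amplitude, rep(1, 5))
  t4m <- make_tone(timbre("five_equal", third_harmonic = FALSE), 100)
  expect_equal(t4m$frequency, 100 * c(1, 2, 4, 5))

  t5 <- make_tone(timbre("bonang"), 100)
  expect_equal(t5$frequency, c(100, 152, 346, 392))
  expect_equal(t5$amplitude, rep(1, 4))

  expect_error(make_tone(timbre("harmonic"), -1), "positive")
  expect_error(timbre("custom", ratios = c(1, 2), weights = 1), "equal length")
  expect_error(timbre("stretched", gamma = 3), "1.5")
})

test_that("chord_spectrum pools per-tone partials without merging", {
  # unison dyad of pure tones: two coincident partials kept distinct
  sp <- chord_spectrum(chord_spec(60, 0), timbre("pure"))
  expect_equal(nrow(sp), 2)
  expect_equal(sp$frequency[1], sp$frequency[2])

  # octave dyad: upper partial 1 coincides with lower partial 2
  sp <- chord_spectrum(chord_spec(60, 12), timbre("harmonic"))
  expect_equal(nrow(sp), 20)
  expect_equal(sort(sp$frequency)[2], sort(sp$frequency)[3])

  # mixed-timbre dyad: 4 harmonic + 4 bonang partials
  sp <- chord_spectrum(chord_spec(60, 7),
                       list(timbre("harmonic", n_harmonics = 4, roll_off = 0),
                            timbre("bonang")))
  expect_equal(nrow(sp), 8)

  # partial count is the sum of per-tone harmonic counts
  sp <- chord_spectrum(chord_spec(48, c(4, 3)), timbre("harmonic", n_harmonics = 7))
  expect_equal(nrow(sp), 21)
  expect_error(chord_spectrum(chord_spec(60, 7), list(timbre("pure"))), "per chord tone")
})

test_that("render_audio implements additive synthesis under the ADSR envelope", {
  env <- adsr_envelope()
  silence <- render_audio(NULL, env, 8000)
  expect_equal(length(silence), round(1.33 * 8000))
  expect_true(all(silence == 0))

  # spectral peak of a rendered 440 Hz partial is at 440 Hz (DFT oracle)
  flat <- adsr_envelope(attack = 0, decay = 0, sustain = 1, release = 0)
  sr <- 8000
  w <- render_audio(tone_spectrum(440, 1), flat, sr)
  spec <- Mod(fft(w))[1:(length(w) / 2)]
  fpeak <- (which.max(spec) - 1) / length(w) * sr
  expect_lt(abs(fpeak - 440), 1.0)
  expect_lte(max(abs(w)), 1)

  # partials above Nyquist are dropped with a warning
  expect_warning(render_audio(tone_spectrum(c(440, 5000), c(1, 1)), flat, 8000),
                 "Nyquist")
})

test_that("write_wav emits a parseable RIFF header", {
  path <- tempfile(fileext = ".wav")
  w <- render_audio(tone_spectrum(440, 1), adsr_envelope(), 8000)
  write_wav(w, path, 8000)
  con <- file(path, "rb")
  on.exit(close(con))
  expect_equal(readChar(con, 4), "RIFF")
  invisible(readBin(con, integer(), 1, 4))
  expect_equal(readChar(con, 8), "WAVEfmt ")
  invisible(readBin(con, integer(), 3, 2))  # fmt size lsb/msb + audio format
  expect_equal(readBin(con, integer(), 1, 2), 1)  # mono
  expect_equal(readBin(con, integer(), 1, 4), 8000)
})

test_that("beat_rate reproduces the equal-temperament beat arithmetic", {
  # 12-TET major third C4-E4: 4th harmonic of E4 vs 5th harmonic of C4
  expect_equal(beat_rate(4 * midi_to_freq(64), 5 * midi_to_freq(60)),
               10.38, tolerance = 0.005)
  # 12-TET perfect fifth C4-G4: 2nd harmonic of G4 vs 3rd harmonic of C4
  expect_equal(beat_rate(2 * midi_to_freq(67), 3 * midi_to_freq(60)),
               0.89, tolerance = 0.005)
  expect_equal(beat_rate(440, 440), 0)
  expect_error(beat_rate(-1, 440), "positive")
})

test_that("estimate_instrument_spectrum recovers synthesis weights", {
  sr <- 16000
  env <- adsr_envelope(attack = 0.05, decay = 0.05, sustain = 0.4,
                       release = 0.1)
  f0 <- 261.6256

  # pure tone: energy concentrated at harmonic 1
  wp <- render_audio(make_tone(timbre("pure"), f0), env, sr)
  ep <- estimate_instrument_spectrum(wp, sr, f0, n_harmonics = 5)
  expect_equal(which.max(ep$amplitude), 1L)
  expect_lt(max(ep$amplitude[-1]) / ep$amplitude[1], 0.01)

  # roll-off tone: relative weights within 10% for harmonics 1-5,
  # monotone decreasing
  tone <- make_tone(timbre("harmonic", n_harmonics = 8, roll_off = 3), f0)
  w <- render_audio(tone, env, sr)
  est <- estimate_instrument_spectrum(w, sr, f0, n_harmonics = 5)
  rel <- est$amplitude / est$amplitude[1]
  truth <- 10^(-3 * log2(1:5) / 20)
  expect_lt(max(abs(rel / truth - 1)), 0.10)
  expect_true(all(diff(rel) < 0))

  # all-zero waveform maps to all-zero amplitudes
  ez <- estimate_instrument_spectrum(numeric(sr), sr, f0, n_harmonics = 3)
  expect_true(all(ez$amplitude == 0))

  expect_error(estimate_instrument_spectrum(numeric(100), 8000, f0 = 5),
               "span")
})
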