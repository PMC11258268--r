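# shared fixtures and small oracles

# random spectrum with positive frequencies/amplitudes
random_spectrum <- function(n = 8, fmin = 100, fmax = 3000) {
  tone_spectrum(runif(n, fmin, fmax), runif(n, 0.1, 1))
}

# brute-force Nadaraya-Watson at a single point (oracle for smooth_profile)
nw_oracle <- function(x0, x, y, bw) {
  w <- exp(-(x - x0)^2 / (2 * bw^2))
  sum(w * y) / sum(w)
}

# dyad profile fixtures reused across tests
harmonic_timbre <- timbre("harmonic", n_harmonics = 10, roll_off = 3)
stretched_timbre <- function(g) timbre("stretched", gamma = g, roll_off = 3)
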