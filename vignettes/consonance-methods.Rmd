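---
title: "Models and methods in consonance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in consonance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific and numerical choices inside the
package: the consonance models and their assumptions, the parameters that
matter, what the synthetic-data generator does and does not emulate, and
the places where the design was genuinely open and a choice had to be
made.

## Stimulus model

Chords are intervallic: a real-valued bass pitch on the MIDI scale plus a
vector of stacked semitone intervals. Pitch maps to frequency through
12-tone equal temperament anchored at A4 = 440 Hz (MIDI 69). Tones are
additive: a set of partials `(f_i, w_i)` determined by the timbre family.

* Harmonic tones: `n_H` partials at integer multiples of `f0`, amplitudes
  `w_i = 10^(-rho * log2(i+1)/20)` — a `rho` dB/octave roll-off. Default
  `n_H = 10`, `rho = 3`.
* Stretched/compressed tones: `f_i = f0 * gamma^log2(i+1)`. `gamma = 2`
  is exactly harmonic; 2.1 and 1.9 are the conventional stretched and
  compressed settings. The admissible range is restricted to [1.5, 2.5];
  outside it the "octave" loses perceptual meaning.
* Pure tones: one partial.
* Five-equal tones: five unit-amplitude harmonics; deleting the 3rd
  harmonic leaves the spectral centroid unchanged, which matters when
  comparing deletion conditions.
* Bonang tones: ratios 1 : 1.52 : 3.46 : 3.92, unit amplitudes — an
  idealization of a Javanese gong-chime spectrum.

Audio rendering applies an ADSR envelope (200 ms linear attack to 1.0,
100 ms exponential decay to 0.8, 30 ms sustain, 1 s exponential release;
total 1.33 s). Two choices here are ours: exponential segments use an
exponential *approach* with time constant one fifth of the segment
duration (common synthesizer semantics; the curvature is unspecified in
the source literature and affects no model output, since models consume
spectra, not waveforms), and partials at or above the Nyquist frequency
are dropped with a warning rather than aliased.

Coincident partials are deliberately **not** merged when pooling a chord's
tones: the pairwise interference term at zero distance is exactly zero, so
keeping duplicates reproduces the aggregate sums verbatim and keeps the
unison case exact.

## Interference model

Pairs of partials are scored by their distance in critical-bandwidth
units, `x = |f2 - f1| / (1.72 ((f1+f2)/2)^0.65)`, through the parametric
kernel `D(x) = (4x e^(1-4x))^2` (zero at unison, maximal at `x = 0.25`,
vanishing for distant pairs). The revised kernel adds a signed slow-beat
term below the boundary `p`:

    D*(x) = (x/p) D(x) - q (1 - x/p)(1 + sin(2 pi x/p - pi/2)),  x < p
    D*(x) = D(x),                                                x >= p

`p` (default 0.096 critical bandwidths) is the distance below which
beating is slow enough to be pleasant; `q` (default 1.632) is the strength
of that pleasantness; both the kernel and its blend are continuous at 0
and at `p`. Aggregation weights each pair by `(A_i A_j)^(r/2)` and
normalizes by `sum(A_k^r)`; the exponent `r` (default 1.359) interpolates
between amplitude weighting (`r = 1`) and the classical intensity
weighting (`r = 2`). `r < 2` makes the model less eager to flatten when
spectral roll-off attenuates upper harmonics. Defaults are the numerically
optimized values and are exposed through `dissonance_params()`.

Degenerate cases are defined, not special-cased away: a single partial
scores 0 (empty pair sum over a positive denominator); `p = 0` reduces
`D*` to `D` by branch. The aggregates are invariant to partial order and
to global amplitude scaling for any `r` — both are asserted as property
tests.

## Harmonicity model

The chord spectrum is projected into a circular pitch-class domain
(default 1200 bins per octave, i.e. 1-cent bins), each partial depositing
an amplitude-scaled circular Gaussian (default sd 6.83 cents, truncated at
±6 sd with octave wrap-around). A harmonic template — the same projection
of an idealized harmonic tone (default 12 harmonics, 3 dB/octave) — is
swept through all circular transpositions, scored by cosine similarity, to
give a virtual-pitch-strength profile. Harmonicity is either the
Kullback–Leibler divergence of that profile (normalized to a probability
distribution) from uniform, in nats with `0 log 0 = 0` — a chord with one
clear implied pitch scores high — or the profile's maximum.

The smearing sd, template size, and template roll-off are conventions of
this modeling lineage rather than quantities fixed by the behavioral
experiments; they are therefore all arguments, and the tests that depend
on them probe qualitative structure (peak locations, invariances) rather
than specific score values. The transposition sweep is computed by FFT
cross-correlation and checked in the tests against a brute-force loop.

## Composite model

`score = -1 * dissonance_revised + 0.837 * harmonicity_hp`, with profiles
median-normalized per experiment (raters calibrate their scale to the
stimuli they hear). An open question in the source material is whether the
components are rescaled before weighting; this package applies the weights
to the **raw** component outputs and normalizes afterwards. The weights
only have meaning relative to that choice, which is why they are bundled
with the harmonicity configuration in `composite_params()`.

## Rating analysis

Trial ratings are z-scored within participant using the sample (n−1)
standard deviation; single-trial or constant-rating participants get
z = 0 (they carry no within-participant information). Profiles are
Nadaraya–Watson estimates with untruncated Gaussian kernels and no
boundary correction — bandwidth 0.2 st for 15-st ranges, 0.035 st for
0.5-st tuning windows, and a product kernel with 1.5 dB/octave on a
roll-off dimension. Grid points whose total kernel weight falls below
1e−12 are returned as `NA`, never silently 0. Confidence bands come from
bootstrapping participants (not trials) with replacement, with the
Gaussian approximation `mean ± 1.96 se`; the per-participant kernel sums
are precomputed once, so a replicate costs a weighted average, not a
re-smooth. Model profiles are smoothed with the same kernel before any
comparison with behavior, so both sides carry the same smoothing bias.

## Peak picking

Profiles are near-interpolated with a cubic smoothing spline at 100
equivalent degrees of freedom (capped at n−4 when the grid is shorter);
peaks are grid points where the spline's first derivative crosses from
positive to negative with second derivative below −range/20, troughs
symmetrically. Adjacent peaks merge (keeping the taller) when the lowest
intervening trough is shallower than α = 0.01 of the range; surviving
peaks must drop by β of the range within 0.5 st on **both** sides
(β = 0.01 for behavioral profiles, 0.05 for deterministic model profiles,
standing in for bootstrap filtering). Two implementation decisions:

* When a valley is too flat for its minimum to qualify as a trough under
  the curvature test, the lowest intervening point is used as the trough
  height. Without this, two peaks separated by a wide flat valley would
  spuriously merge.
* The ±0.5-st sharpness and reliability windows are used **unscaled** on
  all profile ranges. On a 0.5-st tuning window they then span the whole
  profile and the sharpness test degrades gracefully to a depth test
  against each side's minimum. The alternative — shrinking the windows
  with the range — discards the closely spaced tuning peaks that flank a
  just interval (the model's bimodal major-sixth structure sits ~0.15 st
  apart, and a rescaled window cannot see past the intervening valley), so
  it cannot reproduce published tuning-preference peak pairs.
  `rescale_windows = TRUE` restores the other policy.

Peak reliability counts the fraction of bootstrap replicate profiles with
a detected peak within ±0.5 st of each full-sample peak; peaks above 95%
are retained, with location intervals of mean ± 1.96 sd of the matched
(nearest-in-window) replicate locations.

## Model fitting

Model fit is the mean, over experiments, of the Jaccard similarity between
behavioral and model peak sets, where peaks match one-to-one if separated
by less than 2.67% of the interval range (0.4 st on 15 st). The matching
rule — greedy, by increasing pairwise distance, never reusing a peak — is
our decision; the overlap criterion alone does not determine cardinality
when several peaks crowd a tolerance. Empty-vs-empty similarity is defined
as 1 (perfect agreement on "no peaks"), empty-vs-nonempty as 0.
Optimization is box-constrained Nelder–Mead under a logistic
reparameterization, with randomized restarts; a subplex implementation is
not available among the package's allowed dependencies, and because the
objective is piecewise constant the best *evaluated* point (including the
starts) is returned. Default bounds (`p ∈ (0.01, 0.5]`, `q ∈ [0, 5]`,
`r ∈ [0.5, 3]`, `w_h ∈ [0, 3]`) are package conventions, config-exposed.

## Synthetic raters

The generator emulates the dense-rating paradigm's stated sampling
conditions: intervals uniform over the experiment's range, bass uniform
over MIDI 55–65, 1–7 ratings. The response model is ours: latent value =
surface + Gaussian participant intercept (sd 0.3 z) + Gaussian trial noise
(sd 1.0 z), pushed through a monotone Likert map (clip to ±2.5, affine to
[1, 7], round). Participant heterogeneity is intercept-only, which makes
within-participant z-scoring exactly the right correction — deliberately
so, because the generator's job is to exercise the pipeline, not to model
raters fully. It does **not** emulate: scale-use differences beyond the
intercept, musicianship subgroups, cultural variation, attention lapses,
or stimulus-order effects. A green end-to-end test therefore establishes
that the pipeline recovers the structure this generator plants at
realistic noise levels, not that it is robust to everything real raters
do. Trial noise of 1.0 z against profile structure of a few tenths of a z
matches the qualitative signal-to-noise visible in dense-rating raw data,
where single-trial ratings scatter widely around a stable smoothed curve.

## GSP simulation

Chains explore the triad plane `[0.5, 8.5]^2`; each iteration replaces the
active interval with the responder's choice among 400 slider positions,
dimensions alternating (the slider resolution is unspecified in the source
paradigm; 400 makes the discretization error, ~0.02 st, negligible
against the 0.375-st KDE bandwidth). The idealized responder maximizes
utility, either exactly (`argmax`, ties to the first candidate — the
documented tie-break) or through a softmax at temperature 0.05 in utility
units, our stand-in for human response noise. Starting points are uniform
and excluded from aggregation; no further burn-in is discarded, and all
iterations pool equally into an isotropic Gaussian KDE (bandwidth 0.375
st). Within-panel values are additionally rescaled to [0, 1] for display.
The octave-diagonal statistic projects density mass onto `s = i1 + i2`,
takes the band maximum, and refines it by the mass-weighted mean within
one KDE bandwidth — more stable than the raw argmax bin under simulation
noise. Expensive model utilities are precomputed on a grid and bilinearly
interpolated (`grid_utility()`); the interpolation error on these smooth
surfaces is far below the KDE bandwidth.

## Numerical notes and limitations

* The instrument-spectrum estimator follows the subband-envelope recipe
  (half-cosine filters at 0.5-st spacing on MIDI 15–119, Hilbert
  envelopes, `s^0.3` compression, 400 Hz resampling, Gaussian read-out at
  harmonic frequencies with sigma 1.598 Hz). Because that read-out sigma
  is tiny relative to the filter spacing, a harmonic falling midway
  between two filter centers is attenuated by the filter response (up to
  ~cos(pi/4)); recovered amplitudes are accurate to about 10% — the
  precision the tests assert — not to machine precision.
* The quarter-comma-meantone slow-beat rate sometimes quoted for the
  perfect fifth (2.43 Hz) is not reproducible from standard reference
  frequencies (which give ≈2.48 Hz); the package asserts only the
  12-TET beat rates, which are exact arithmetic.
* Fitting to real behavioral archives is supported mechanically (CSV in,
  peaks out) but the package ships no behavioral data; all shipped
  expectations are against synthetic raters or analytic fixtures. The fit
  CLI reads a JSON experiment manifest (no YAML parser is available in
  the dependency budget).
* Bootstrap and split-half computations hold a grid × trials kernel
  matrix in memory per participant batch; at the default 1000-point grid
  and ~10^4 trials this is tens of MB — fine on a laptop, but worth
  chunking for much larger designs.
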