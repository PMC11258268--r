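# consonance

Psychoacoustic modeling of musical consonance over continuous intervallic
spaces.

Why do some combinations of simultaneously sounded tones sound pleasant
(consonant) and others harsh (dissonant)? The two leading psychoacoustic
accounts make different predictions once you manipulate *timbre*:
**interference** theories locate dissonance in beating between nearby
partials of the combined spectrum, so moving or attenuating the partials
should reshape consonance; **harmonicity** theories locate consonance in
the match between the chord's spectrum and an idealized harmonic series,
and are comparatively insensitive to such manipulations. This package
implements both model families, a composite of the two, and the full
experimental-analysis pipeline used to compare them against dense
behavioral ratings — so that model predictions and (real or simulated)
rating data can be pushed through the identical machinery.

It is aimed at auditory-perception and music-cognition researchers who
want to generate spectral stimuli, score chords under competing consonance
models, and analyze continuous rating or adaptive-sampling experiments.

## The models

A chord is a bass pitch (MIDI scale, `f = 440·2^((p−69)/12)`) plus stacked
intervals in semitones; its spectrum is the pooled set of partials
`(f_i, A_i)` of its tones (harmonic, stretched/compressed `f_i = f0·γ^log2(i+1)`,
pure, equal-weight, or bonang-type inharmonic spectra).

**Interference** (Hutchinson–Knopoff lineage). Pair distances are expressed
in critical bandwidths, `x = |f2−f1| / (1.72 ((f1+f2)/2)^0.65)`, scored by
the kernel `D(x) = (4x e^(1−4x))²`, and aggregated as

    Dissonance = Σ_{i<j} (A_i A_j)^(r/2) · D*(x_ij) / Σ_k A_k^r

The revised kernel `D*` equals `D` above a slow-beat boundary `p`, while
below it a negative (pleasant) slow-beat term is blended in with strength
`q`; the amplitude exponent `r` interpolates between amplitude (`r = 1`)
and intensity (`r = 2`) weighting. Defaults: `p = 0.096`, `q = 1.632`,
`r = 1.359`.

**Harmonicity** (Milne / Harrison–Pearce lineage). The spectrum is smeared
into a circular pitch-class distribution (1200 bins/octave, Gaussian sd
6.83 cents), compared by cosine similarity against every transposition of
a harmonic template, and summarized either by the Kullback–Leibler
divergence of the resulting virtual-pitch profile from uniform (pitch
clarity) or by its maximum.

**Composite**: `score = −1 · Dissonance + 0.837 · Harmonicity`, median-
normalized per experiment.

The analysis side provides within-participant z-scoring, Nadaraya–Watson
kernel smoothing (0.2 st bandwidth on 15-st ranges; 0.035 st on
0.5-st tuning windows; 2D interval×roll-off product kernels), participant-
level bootstrap confidence bands, a smoothing-spline peak picker with
trough-merge and sharpness rules plus bootstrap peak reliability, a
peak-Jaccard model-fit objective with derivative-free optimization, a
dense-rating simulator, and a Gibbs-Sampling-with-People (GSP) chain
simulator with KDE aggregation for triad spaces.

## Worked example

```r
library(consonance)
cp <- composite_params()
for (iv in c(7, 11, 12)) {
  sp <- chord_spectrum(chord_spec(60, iv), timbre("harmonic"))
  cat(sprintf("interval %2g: interference %.4f, composite %.4f\n", iv,
      dissonance_revised(sp, cp$dissonance), composite_score(sp, cp)))
}
```

```
interval  7: interference 0.0469, composite 0.6430
interval 11: interference 0.2591, composite 0.2419
interval 12: interference 0.0093, composite 0.8396
```

The perfect fifth (7 st) and octave (12 st) beat little and score as
consonant; the major seventh (11 st) places many partials within a
critical bandwidth of each other and scores low. Stretching the tones'
partials (γ = 2.1) moves the model's preferred "octave" to the stretched
octave at `12·log2(2.1) ≈ 12.84` st:

```r
grid <- seq(10, 14.5, length.out = 500)
raw  <- score_profile("composite", grid, timbres = timbre("stretched", gamma = 2.1))
prof <- model_profile(normalize_profile(raw), grid, 0.2)
find_peaks(prof, peak_pick_config(beta = 0.05))
```

```
  location       height
1 11.94790 -0.004004311
2 12.84068  0.289869726
```

The dominant peak sits at 12.84 st — a consonance maximum at an interval
no harmonic tuning system contains, the key dissociation between the
interference and harmonicity mechanisms.

## Command line

```sh
Rscript inst/cli/consonance synth --bass 60 --intervals 7 --timbre harmonic --rolloff 3 --out chord.wav
Rscript inst/cli/consonance score --model composite --bass 60 --intervals 12
Rscript inst/cli/consonance simulate-raters --timbre harmonic --n 200 --seed 1 --out ratings.csv
Rscript inst/cli/consonance profile --ratings ratings.csv --bandwidth 0.2 --nboot 1000 --seed 1 --out profile.csv
Rscript inst/cli/consonance peaks --profile profile.csv --out peaks.csv
```

Every command writes a JSON run manifest next to its output.

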