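---
title: "Methods: generative musical stimuli and synthetic dyadic fNIRS analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: generative musical stimuli and synthetic dyadic fNIRS analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadtune)
```

# Overview

`dyadtune` implements, as a tested and reusable chain, the computational
methodology of a dyadic music-listening fNIRS hyperscanning experiment: two
participants listen together to consonant chord-progression music (or a
note-shuffled control) while a switchable smart glass either reveals or hides
the partner's face, giving a 2 x 2 block design (face x chord progression).
The package covers:

1. **Stimulus generation** — procedural composition of the 12 ii–V–I–vi
   exemplars and their shuffled controls, rendered to audio.
2. **Acoustic characterization** — rhythm and timbre features of the two
   stimulus conditions and their statistical comparison.
3. **Synthetic dyadic fNIRS** — a forward model producing raw
   three-wavelength optical-density recordings with known ground truth.
4. **Preprocessing** — Beer–Lambert inversion, wavelet detrending, PCA
   spatial global mean filtering, HbDiff combination.
5. **GLM** — canonical-HRF block design, per-channel betas, group contrasts,
   ratings-as-covariate association.
6. **Cross-brain coherence** — complex-Gaussian wavelet transform,
   per-condition partner correlation, 10–20 s band comparison, scrambled-pair
   null.
7. **Behavior** — Kruskal–Wallis, Games–Howell and Bonferroni pairwise
   analysis of 0–5 connectedness ratings.

Because the real dataset is not required, every downstream stage is validated
by parameter recovery against the synthetic generator's ground truth.

# Stimulus model

Each chord-progression (CP) exemplar is 15 s at 140 BPM and has four tracks:
a pentatonic half-note melody, half-note seventh chords following
ii7–V7–Imaj7–vi7 root motion (e.g., Dm7–G7–Cmaj7–Am7 in C major), a bass
playing quarter notes on the chord roots an octave below, and drums (ride
cymbal on every beat, kick on every half note). The progression cycles; in
the fourth cycle, after ii and V, the tonic major seventh is sustained to the
end of the window — at 140 BPM a 15 s window holds 17.5 half-note slots, so
cycles 1–3 fill 12 slots and the final resolution fills the rest. Drum hits
are placed only where the full note value fits inside the stimulus, which
yields 35 ride and 17 kick events.

The four melody templates are fixed eight-slot contours over the major
pentatonic degrees {1, 2, 3, 5, 6}, transposed per key; the published
melodies are not notated in a recoverable form, so these are reproducible
stand-ins with the documented properties (non-syncopated, half notes,
pentatonic). One of the four is randomly assigned to each of the 12 major
keys.

The no-chord-progression (NCP) control displaces every tonal note
(melody, chords, bass) by an independent uniform offset of 0.25–2 s with
random sign, wrapping around the stimulus, while the drum track is untouched.
Onset-permutation is available as an alternative (`method = "permute"`);
per-note jitter is the default because it matches the printed displacement
range directly. Both destroy harmonic and tonal-rhythmic context while
preserving the drum grid, tempo and the per-track multiset of pitches and
durations.

Rendering uses additive harmonic synthesis with per-track ADSR envelopes, a
band-passed noise burst (80 ms decay) for the ride and a 60 Hz decaying sine
for the kick. Each note partial gets a deterministic pseudo-random phase
(hashed from pitch, onset and partial number) so that overlapping
same-pitch notes add incoherently and the energy budget survives temporal
shuffling. The mix is peak-normalized to 0.89 full scale; rendering is
bit-identical given score, patch and seed.

# Acoustic features

The short-time Fourier front end uses 46 ms Hann windows with a 10 ms hop on
mono audio. For the fluctuation (modulation) spectrum the STFT bins are
grouped into 40 log-spaced envelope bands, band envelopes are de-meaned,
zero-padded (4x) and Fourier-transformed along time, and the band modulation
magnitudes are summed; the grid is restricted to 0–10 Hz. The spectrogram is
first scaled to unit RMS, so modulation magnitudes are loudness-referenced:
the rendered conditions differ in crest factor, and peak-normalized audio
would otherwise leak an arbitrary gain difference into an "absolute"
modulation magnitude while the original stimuli were level-matched in the
mixing stage.

Features:

* **Peak magnitude** — maximum of the fluctuation spectrum.
* **Peak-to-median ratio** — the same maximum relative to the median
  magnitude (rhythmic salience; scale-free).
* **Fluctuation entropy** — Shannon entropy of the normalized modulation
  distribution divided by `log(bins)`, in [0, 1].
* **Tempo** — 60 x the strongest modulation peak inside the 30–300 BPM
  window, with parabolic peak interpolation (the zero-padded grid plus
  interpolation brings the quantization error well under 1 BPM).
* **Pulse clarity** — the onset envelope is the positive spectral flux per
  frame; its autocorrelation is normalized by lag 0; candidate lags are the
  local maxima at lags of 0.2 s or more, the tactus lag is selected with the
  standard log-Gaussian preferred-tempo weighting (centre 0.5 s, sd 0.55
  octaves), and the unweighted correlation at that lag is reported. The
  weighting matters: the CP condition's global autocorrelation maximum sits
  at the half-note lag (all tracks align there), but the perceived-beat
  construct refers to the tactus, where the CP accent alternation *lowers*
  the correlation and the drum-only periodicity of the shuffled control
  raises it — reproducing the reported direction (NCP > CP).
* **Spectral flux** — mean L2 norm of positive differences between
  consecutive L1-normalized frames.
* **RMS (dBFS)** and **spectral centroid** — standard definitions; silence
  reports `-Inf` / flagged `NA`.

The CP-vs-NCP comparison is a pooled two-sample t-test per feature
(df = 12 + 12 − 2 = 22), signed CP − NCP. On the regenerated default-seed
set the four rhythm features reproduce the reported directions (peak
magnitude and peak-to-median higher for CP; entropy and pulse clarity higher
for NCP) and the estimated tempo is 140 ± 0.1 BPM for every exemplar.
Absolute feature magnitudes depend on the synthesizer timbre and are not
comparable to values measured from the original hardware-synth audio; only
directions, the df bookkeeping and the tempo are asserted.

# Synthetic dyadic fNIRS

The paradigm builder produces `n_runs = 8` runs, each containing the four
conditions once in per-run shuffled order as 15 s task blocks each followed
by 15 s rest — 960 s (16 min) in total at 30 Hz. The condition
counterbalancing scheme of the original sessions is not documented, so a
seeded per-run shuffle stands in.

Per channel the forward model is

```
OxyHb(t)  =  sum_c beta[c] * (boxcar_c * HRF)(t)  +  global(t)
            +  coupled(t)  +  noise(t)
deOxyHb(t) = -gamma * (task + coupled)(t)  +  own global(t)  +  noise(t)
```

with `gamma = 1/3`: task-evoked deoxyhemoglobin is modelled as a scaled
anticorrelated copy, which produces a physiologically shaped HbDiff without
claiming quantitative fidelity. Systemic globals are cardiac (1 Hz, amp
0.3), respiratory (0.25 Hz, 0.2) and Mayer-wave (0.1 Hz, 0.2) sinusoids with
random phases plus a random-walk drift (step sd 0.005), identical across
channels within a participant — exactly the structure a spatial global mean
filter is designed to remove. Channel noise is white (sd 0.2, about half the
task signal's sd). Default condition amplitudes are 1.0 for face + chord
progression and 0.5 for the other three conditions, on 12 "signal" channels
whose gains span 0.6–1.4 (the remaining 17 of the 29 channels carry no task
response; montage geometry is not modelled, channels are abstract indices).

Cross-brain coupling is a band-limited Gaussian process at a 15 s period
(Gaussian spectral envelope, relative bandwidth 1/6), mixed as
`sqrt(r) * shared + sqrt(1-r) * own` into both partners' designated channels
(three pairs by default) only during face + chord blocks, so the partner
correlation of the injected component equals the coupling strength
`r = 0.6`; its amplitude is 0.3. Chromophores map to optical density at 780,
805 and 830 nm through a nominal extinction matrix (805 nm near-isosbestic);
absolute calibration is irrelevant since concentrations are relative with
unit pathlength.

What the generator does **not** emulate: photon-transport geometry, motion
artifacts, skin-blood-flow heterogeneity across channels, non-Gaussian
physiological noise, and any anatomical channel identity. Passing
parameter-recovery tests therefore demonstrate the *analysis chain's*
correctness, not robustness to every artifact class of real recordings.

# Preprocessing

**Beer–Lambert inversion** solves the 3-wavelength x 2-chromophore least
squares per channel and timepoint; the forward/inverse round trip is exact
for any well-conditioned extinction matrix (condition number below 1e6 is
enforced).

**Wavelet detrending** removes the per-channel linear trend, then
decomposes with an orthogonal symlet (sym4) DWT (circular convolution after
reflection padding), zeroes the approximation at the level whose periods
reach the cutoff (default 128 s), and reconstructs. The linear pre-step
matters numerically: coarse-level wavelets have supports comparable to the
recording, so a raw trend would otherwise bleed boundary artifacts. A pure
ramp detrends to machine zero; a 10 s-period signal passes with correlation
above 0.999.

**PCA spatial global mean filter**: principal components of the
time x channel matrix whose spatial loadings are near-uniform (uniformity
score `|mean loading| * sqrt(n_channels)` of 0.7 or more) are projected out,
searched largest-variance-first until the examined components account for
the variance budget (0.8). The variance budget bounds the search depth
rather than capping what may be removed — a global component that carries
99% of the variance must still be removable. The output is exactly
orthogonal to every removed component. A consequence worth knowing when
designing simulations: a task activation pattern that is itself spatially
near-uniform across *all* channels is indistinguishable from a systemic
global by a spatial filter; the default ground truth activates 12 of 29
channels (uniformity 0.63) and is untouched.

**HbDiff**: the analysis signal combines the two chromophores. Task-evoked
deoxyhemoglobin is negative-going, so the reliability-optimizing combination
is `oxy - deoxy` (the default); the literal `oxy + deoxy` sum is available
by `mode = "sum"`. Under the default and the simulator's `gamma`, HbDiff
task amplitude is `(1 + gamma) * beta`.

Every stage appends its name and parameters to a provenance vector on the
`chromophore_series`.

# GLM

The canonical HRF is a difference of gamma densities parameterised by their
modes — response peak at 6 s (shape 7, rate 1), undershoot at 16 s, ratio
1/6, 32 s support, unit peak. Parameterising by the mode keeps the
documented "peak at 6 s" literally true of the kernel. The design has one
HRF-convolved boxcar per condition plus an intercept; drift columns are
unnecessary because detrending precedes the GLM. Per-channel OLS gives the
beta values; the second level is a one-sample t-test across participants of
the per-participant contrast value (df = n − 1), uncorrected p-values by
default with Benjamini–Hochberg available via `stats::p.adjust` downstream.
Run-level ratings enter as covariates through the participant's
contrast-weighted mean condition rating, regressed against the neural
contrast per channel.

With the default ground truth and 20 simulated dyads the fitted betas
correlate with the injected ones at r above 0.9 and the face_chord −
face_nochord contrast is significant on every signal channel.

# Cross-brain coherence

**Scales.** The dyadic grid uses periods `(1/f_max) * 2^(j/voices)`,
`j = 0..15`, for 0.4–0.025 Hz with 4 octaves and 4 voices: 16 scales,
shortest period 2.5 s, adjacent ratio exactly `2^(1/4)` (longest period
33.6 s). The alternative reading — 16 periods spanning both endpoint
frequencies inclusively, ratio `16^(1/15)` — is recorded in the scale-set
metadata; the dyadic convention was chosen because it is the standard CWT
grid and keeps the voice spacing exact.

**Task removal.** Before the transform, signals are residualized on the
design *augmented with its own detrended regressors and a linear trend*.
This is a correctness point discovered by construction: detrending and
global filtering remove the slow content of the task regressors from the
data, so residualizing a preprocessed signal on the raw design leaves a
task-locked leakage term. Both partners share that term (their condition
amplitudes are proportional), and at the 15 s scale the block cycle has
strong harmonics, so the leakage masquerades as near-perfect cross-brain
coherence in *every* condition. The leakage lies exactly in the span of the
raw regressors, their detrended images and a linear trend; projecting that
span out (SVD-based, robust to the near-collinearity) removes it, while the
injected band-limited coupling — block-gated noise, not a boxcar — survives
with correlation above 0.9.

**Transform.** Analytic complex-Gaussian-derivative kernel of order 4 in the
frequency domain, `(sw)^4 exp(-(sw)^2/2)` on positive frequencies,
peak-normalized per scale; scale `s = sqrt(4)/omega_0` for target angular
frequency `omega_0`, so the ridge of a sinusoid falls on the nearest scale.

**Coherence.** Per scale, the Pearson correlation of the partners'
coefficient magnitudes over the concatenated samples of a condition's
blocks (`statistic = "real"` correlates real parts instead). Cone-of-
influence handling excludes one e-folding time (`sqrt(2) s`, about
0.45 x period) at the edges of the contiguous series the CWT was computed
on. Excluding an e-folding at every *block* edge instead would leave no
valid samples at periods above ~16 s inside 15 s blocks and would erase the
10–20 s analysis band entirely; since the transform is continuous across
block boundaries, only genuine series edges produce edge artifacts.

**Band test.** Per dyad, coherence is averaged over channel pairs and over
scales with periods in 10–20 s, and conditions are compared by a paired t
across dyads (the pairing unit; its df is n_dyads − 1). The scrambled-pair
null re-runs the identical pipeline with partner B drawn from a different
dyad (derangement sampling), aligned to partner A's paradigm. With the
default generator, face + chord exceeds every other condition for true
pairs (p < 0.05, 20 dyads) and no such difference survives scrambling.

# Behavior

Ratings are integers 0–5; 0 is a nonanswer and is excluded. Analyses run on
per-participant condition means: a tie-corrected Kruskal–Wallis omnibus
(df = groups − 1), Games–Howell post hocs (Welch–Satterthwaite df,
studentized-range statistic `q = |m1-m2| / sqrt((s1^2/n1 + s2^2/n2)/2)`
referred to `stats::ptukey`, which computes the distribution by numerical
integration), and Welch pairwise t-tests with Bonferroni multiplication by
the number of pairs. The synthetic ratings generator draws integer ratings
around condition means 3.9 / 3.1 / 2.9 / 2.1 (face_chord … noface_nochord)
with baseline 2.6 and sd 0.9 — the reported qualitative ordering with a
dial-scale-plausible spread; with 40 raters the omnibus rejects far below
0.001 and the face_chord vs noface_nochord contrast is the most extreme
pairwise q. Baseline rows keep a retroactive flag (60% of raters).

# Problem sizes and determinism

The packaged analyses run at the study's native scale: 12 + 12 stimuli at
22.05 kHz, 29 channels at 30 Hz for 960 s, 20 dyads for the
parameter-recovery properties, 40 raters for the behavioral power check.
Test fixtures use fewer channels, runs or dyads where a property does not
depend on scale. All randomness flows from explicit integer seeds through a
single derivation (`root seed + stage label -> child seed`), and every
simulated artifact records its seed; reruns with the same configuration are
bit-reproducible, which the pipeline manifest (md5 of each stage product)
makes checkable.

# Known limitations

* The synthesizer is a plain additive stand-in; absolute acoustic feature
  magnitudes are timbre-dependent and not comparable across synthesizers.
* The melody templates and chord voicings are reproducible stand-ins, not
  the published note sequences.
* The deoxyhemoglobin model is a fixed anticorrelated fraction; no venous
  delay or amplitude heterogeneity.
* Coherence uses magnitude correlation; complex coherency with phase
  information is not implemented (real-part correlation is the only
  alternative statistic).
* No motion artifacts, short-separation regression, or anatomical
  registration; channels are indices, not cortical locations.
* The paired band test treats dyads as exchangeable; channel-pair-level
  pairing conventions (which produce different dfs) can be obtained by
  aggregating the long-format output differently.
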