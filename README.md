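# dyadtune

Analysis tools for a dyadic music-listening fNIRS hyperscanning paradigm:
two people listen together to consonant chord-progression music — or a
note-shuffled control — while a switchable smart glass shows or hides the
partner's face (a 2 × 2 block design: face × chord progression). The package
implements the full computational chain of that experiment so that every
stage can be validated without access to human recordings:

* **Stimuli** — procedural composition of the 12 ii–V–I–vi exemplars
  (one per major key, 140 BPM, 15 s; e.g., Dm7–G7–Cmaj7–Am7 in C) and their
  controls made by temporally shuffling the tonal tracks (0.25–2 s) while
  leaving the drums untouched; rendering to WAV, export to MIDI/JSON.
* **Acoustic features** — STFT (46 ms / 10 ms Hann), fluctuation
  (modulation) spectrum, peak magnitude and peak-to-median ratio,
  fluctuation entropy, pulse clarity, tempo, spectral flux, RMS (dBFS),
  centroid; pooled-t comparison of the two conditions (df = 22 for 12 vs 12).
* **Synthetic dyads** — forward model of raw 3-wavelength (780/805/830 nm)
  optical density at 30 Hz over 29 channels: HRF-convolved block responses,
  systemic globals (cardiac/respiratory/Mayer/drift), channel noise, and a
  band-limited cross-brain coupled process injected only in the
  face + chord condition (partner correlation = coupling strength).
* **Preprocessing** — modified Beer–Lambert inversion
  (`od = ε · [HbO, HbR]ᵀ`, least squares per timepoint), sym4 wavelet
  detrending (cutoff 128 s), PCA spatial global mean filter
  (uniform-loading components projected out), HbDiff combination.
* **GLM** — canonical double-gamma HRF (peak 6 s, undershoot 16 s,
  ratio 6), per-channel OLS betas, one-sample group contrasts across
  participants, ratings-as-covariate regression.
* **Cross-brain coherence** — complex-Gaussian (order 4) CWT on 16 dyadic
  scales (0.4–0.025 Hz, 4 octaves × 4 voices, shortest period 2.5 s),
  task-regressor removal, per-condition Pearson correlation of partner
  coefficient magnitudes over concatenated blocks, paired comparison of the
  10–20 s band, scrambled-pair (derangement) null.
* **Behavior** — 0–5 connectedness ratings (0 = nonanswer): Kruskal–Wallis
  omnibus, Games–Howell post hocs (Welch df + studentized range), Bonferroni
  pairwise t, condition means.

See the methods vignette (`vignettes/dyadic-music-fnirs.Rmd`) for the model
and every numerical choice.

## Worked example

```r
library(dyadtune)

## one chord-progression exemplar and its acoustic profile
score <- compose_chord_progression("C", melody_id = 1)
clip  <- render_audio(score)
extract_features(clip)[, c("tempo_bpm", "peak_to_median", "pulse_clarity")]
#>   tempo_bpm peak_to_median pulse_clarity
#> 1  140.0804       25.10343     0.7985755
```

The estimated tempo recovers the composed 140 BPM; the high peak-to-median
ratio says the beat-rate modulation dominates the fluctuation spectrum.

```r
## the full 12 + 12 stimulus set, compared like the acoustic table
sets <- build_stimulus_sets(1)
feats <- do.call(rbind, lapply(names(sets$cp), function(k) rbind(
  extract_features(render_audio(sets$cp[[k]])),
  extract_features(render_audio(sets$ncp[[k]])))))
is_cp <- grepl("^chord_progression", feats$label)
compare_conditions(feats[is_cp, ], feats[!is_cp, ])[c(1, 2, 3, 4), c("feature", "t", "df", "p")]
#>          feature         t df            p
#> 1 peak_magnitude  17.97106 22 1.230519e-14
#> 2 peak_to_median  23.82168 22 3.348947e-17
#> 3  fluct_entropy -11.20934 22 1.454855e-10
#> 4  pulse_clarity -12.26062 22 2.628573e-11
```

Positive t means chord progression > control: the intact progressions carry
stronger and more salient low-frequency modulation, while the shuffled
controls have flatter (higher-entropy) modulation spectra and clearer
surface-level pulse — the qualitative signature of hierarchical harmonic
structure.

```r
## a small synthetic hyperscanning experiment end-to-end
report <- run_pipeline(default_config(seed = 1, n_keys = 2, n_dyads = 4))
report
#> <pipeline_report>
#>   stimuli: 4 clips, 8 features compared
#>   ratings omnibus: H(4) = 77.32, p = 6.44e-16
#>   coherence band 10-20 s (face_chord - face_nochord): t(3) = 6.17, p = 0.00858
#>   contrast channels p < 0.05: 12 of 29
```

The omnibus test rejects because the synthetic raters prefer
face + chord progression; the 10–20 s cross-brain coherence band separates
the face + chord condition (where coupling is injected) from the matched
face condition without it; and the group contrast lights up exactly the 12
channels that carry a simulated response difference.

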