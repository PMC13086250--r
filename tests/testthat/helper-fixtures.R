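## Shared fixtures: tiny deterministic objects rebuilt at test time.

## a short paradigm (n_runs runs of the standard 4 task + 4 rest layout)
tiny_paradigm <- function(n_runs = 1, seed = 1) {
  make_paradigm(n_runs = n_runs, order_seed = seed)
}

## ground truth scaled down to a few channels for fast simulations
tiny_truth <- function(n_channels = 4, noise_sd = 0, coupling = FALSE,
                       strength = 0.6, period_s = 15) {
  tr <- default_ground_truth(n_channels = n_channels, noise_sd = noise_sd)
  tr$globals <- list()
  tr$drift_sd <- 0
  ## alternate beta signs: with every channel active, an all-positive pattern
  ## would itself look spatially uniform to the global filter
  flip <- (-1)^(seq_len(n_channels) - 1)
  for (p in 1:2) tr$beta_true[p, , ] <- tr$beta_true[p, , ] * flip
  tr$coupling <- if (coupling) {
    data.frame(channel_a = 1L, channel_b = 1L, period_s = period_s,
               strength = strength, condition = "face_chord")
  } else tr$coupling[0, ]
  tr
}

## a pure sine clip
sine_clip <- function(freq, dur = 1, sr = 8000, amp = 0.5) {
  t <- seq(0, dur, by = 1 / sr)[-1]
  dyadtune:::new_audio_clip(amp * sin(2 * pi * freq * t), sr, "sine")
}
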