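## Software synthesizer: additive harmonic synthesis for the tonal tracks,
## enveloped noise/sine for the drums. A software stand-in with a plain,
## consonant timbre; rendering is bit-reproducible given patch and seed.

#' Default synthesizer patch
#'
#' Per-track harmonic amplitude vectors and ADSR envelopes for the tonal
#' tracks, plus drum model parameters: the ride cymbal is a band-passed noise
#' burst with an 80 ms decay, the kick a 60 Hz decaying sine thump.
#'
#' @return a `synth_patch` list
#' @export
default_patch <- function() {
  structure(list(
    melody = list(harmonics = c(1, 0.5, 0.25, 0.12, 0.06),
                  adsr = c(attack = 0.01, decay = 0.08, sustain = 0.7,
                           release = 0.15)),
    chords = list(harmonics = c(1, 0.4, 0.2, 0.1, 0.05),
                  adsr = c(attack = 0.01, decay = 0.10, sustain = 0.6,
                           release = 0.20)),
    bass   = list(harmonics = c(1, 0.3, 0.1),
                  adsr = c(attack = 0.005, decay = 0.05, sustain = 0.8,
                           release = 0.10)),
    drums  = list(ride_decay_s = 0.08, ride_band_hz = c(4000, 9000),
                  kick_freq_hz = 60, kick_decay_s = 0.12)
  ), class = "synth_patch")
}

midi_to_hz <- function(pitch) 440 * 2^((pitch - 69) / 12)

## ADSR amplitude envelope sampled at sr over a note of length dur (the
## release extends past the nominal duration).
adsr_envelope <- function(dur, adsr, sr) {
  a <- adsr[["attack"]]; d <- adsr[["decay"]]
  s <- adsr[["sustain"]]; r <- adsr[["release"]]
  n <- max(1L, round((dur + r) * sr))
  t <- (seq_len(n) - 1) / sr
  env <- numeric(n)
  seg <- t < a
  env[seg] <- if (a > 0) t[seg] / a else 1
  seg <- t >= a & t < a + d
  env[seg] <- 1 - (1 - s) * (t[seg] - a) / d
  seg <- t >= a + d & t < dur
  env[seg] <- s
  seg <- t >= dur
  env[seg] <- s * pmax(0, 1 - (t[seg] - dur) / r)
  env
}

new_audio_clip <- function(samples, sample_rate, label = "") {
  structure(list(samples = samples, sample_rate = sample_rate, label = label),
            class = "audio_clip")
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip> %s: %.2f s at %d Hz, peak %.3f\n", x$label,
              length(x$samples) / x$sample_rate, as.integer(x$sample_rate),
              if (length(x$samples)) max(abs(x$samples)) else 0))
  invisible(x)
}

#' Render a stimulus score to audio
#'
#' Additive harmonic synthesis for the melody, chord and bass tracks and
#' enveloped noise/sine bursts for the drums, mixed to a mono waveform. The
#' drum noise is drawn once per render from `rng_seed`, so rendering is
#' bit-identical under a fixed score, patch and seed.
#'
#' @param score a `stimulus_score`
#' @param patch a `synth_patch`, see [default_patch()]
#' @param sample_rate output rate in Hz (>= 8000; default 22050)
#' @param rng_seed seed for the ride-cymbal noise burst
#' @param normalize if `TRUE` (default) scale the mix so the peak sits at 0.89
#'   of full scale (no clipping); `FALSE` leaves raw summed amplitudes
#' @return an `audio_clip` (mono samples in \[-1, 1\], sample rate, label)
#' @export
render_audio <- function(score, patch = default_patch(), sample_rate = 22050,
                         rng_seed = 1, normalize = TRUE) {
  stopifnot(inherits(score, "stimulus_score"))
  if (!is.list(patch) || length(patch) == 0) stop("empty synth patch")
  if (sample_rate < 8000) stop("sample_rate must be >= 8000 Hz")
  sr <- sample_rate
  tail_s <- 0.3  # longest release / drum decay
  ## buffer runs to the last sounding sample so no note energy is truncated
  last_end <- if (nrow(score$events)) {
    max(score$events$onset + score$events$duration)
  } else 0
  n <- as.integer(round((max(score$length_s, last_end) + tail_s) * sr))
  out <- numeric(n)
  ev <- score$events

  ## deterministic percussion waveforms, shared by all hits of a kind
  drums <- patch$drums
  ride_len <- max(1L, round(4 * drums$ride_decay_s * sr))
  ride_noise <- with_seed(rng_seed, stats::rnorm(ride_len))
  band <- drums$ride_band_hz / (sr / 2)
  bf <- signal::butter(2, pmin(band, 0.999), type = "pass")
  ride_wave <- as.numeric(signal::filter(bf, ride_noise)) *
    exp(-(seq_len(ride_len) - 1) / (drums$ride_decay_s * sr))
  ride_wave <- ride_wave / max(abs(ride_wave), 1e-12) * 0.8
  kick_len <- max(1L, round(4 * drums$kick_decay_s * sr))
  tk <- (seq_len(kick_len) - 1) / sr
  kick_wave <- sin(2 * pi * drums$kick_freq_hz * tk) *
    exp(-tk / drums$kick_decay_s)

  add_at <- function(buf, x, start) {
    i0 <- start + 1L
    i1 <- min(length(buf), start + length(x))
    if (i1 >= i0) buf[i0:i1] <- buf[i0:i1] + x[seq_len(i1 - i0 + 1L)]
    buf
  }

  for (i in seq_len(nrow(ev))) {
    start <- as.integer(round(ev$onset[i] * sr))
    if (ev$track[i] == "drums") {
      wave <- if (ev$pitch[i] == DRUM_KICK) kick_wave else ride_wave
      out <- add_at(out, wave * ev$velocity[i], start)
    } else {
      tp <- patch[[ev$track[i]]]
      if (is.null(tp)) stop("patch has no entry for track '", ev$track[i], "'")
      env <- adsr_envelope(ev$duration[i], tp$adsr, sr)
      t <- (seq_along(env) - 1) / sr
      f0 <- midi_to_hz(ev$pitch[i])
      wave <- numeric(length(env))
      for (k in seq_along(tp$harmonics)) {
        fk <- k * f0
        if (fk < sr / 2) {
          ## deterministic per-note/partial phase hash: overlapping notes of
          ## the same pitch add incoherently, keeping the energy budget
          ## additive under temporal shuffling
          ph <- 2 * pi * ((sin(ev$pitch[i] * 12.9898 + ev$onset[i] * 78.233 +
                                 k * 37.719) * 43758.5453) %% 1)
          wave <- wave + tp$harmonics[k] * sin(2 * pi * fk * t + ph)
        }
      }
      ## scale so a full chord stays in range before normalization
      out <- add_at(out, wave * env * ev$velocity[i] * 0.2, start)
    }
  }

  if (normalize) {
    peak <- max(abs(out))
    if (peak > 0) out <- out * (0.89 / peak)
  }
  new_audio_clip(out, sr, paste(score$condition, score$key))
}
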