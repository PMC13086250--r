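## Rhythm and timbre features of the stimuli: STFT spectrogram, fluctuation
## (modulation) spectrum, pulse clarity, spectral flux / RMS / centroid, and
## the chord-progression vs control comparison table.

#' Short-time Fourier magnitude spectrogram
#'
#' Hann-tapered STFT of a mono clip with 46 ms windows and a 10 ms hop by
#' default.
#'
#' @param clip an `audio_clip`
#' @param window_ms analysis window in milliseconds
#' @param hop_ms hop between frames in milliseconds
#' @return a `spectrogram`: list with `mag` (frequency x frame magnitudes),
#'   `freq` (Hz), `time` (s, frame centers), `frame_rate` (frames/s) and
#'   `sample_rate`
#' @export
stft_spectrogram <- function(clip, window_ms = 46, hop_ms = 10) {
  stopifnot(inherits(clip, "audio_clip"))
  x <- as.numeric(clip$samples)
  sr <- clip$sample_rate
  n <- max(4L, as.integer(round(sr * window_ms / 1000)))
  hop <- max(1L, as.integer(round(sr * hop_ms / 1000)))
  if (length(x) < n) stop("clip shorter than one analysis window")
  sp <- signal::specgram(x, n = n, Fs = sr, window = signal::hanning(n),
                         overlap = n - hop)
  structure(list(mag = abs(sp$S), freq = as.numeric(sp$f),
                 time = as.numeric(sp$t), frame_rate = sr / hop,
                 sample_rate = sr),
            class = "spectrogram")
}

#' Fluctuation (modulation) spectrum
#'
#' Groups the STFT bins into log-spaced envelope bands, Fourier-transforms the
#' de-meaned band envelopes along time (zero-padded for a fine modulation-
#' frequency grid), and sums the band modulation magnitude spectra. The grid
#' is restricted to 0-10 Hz, the range of musical rhythm.
#'
#' @param spec a `spectrogram` with at least two frames
#' @param n_bands number of log-spaced envelope bands (default 40)
#' @param f_mod_max upper modulation frequency in Hz (default 10)
#' @return a `fluctuation_spectrum`: list with `freq` (Hz, strictly
#'   increasing) and `mag` (summed nonnegative modulation energy, a.u.)
#' @export
fluctuation_spectrum <- function(spec, n_bands = 40, f_mod_max = 10) {
  stopifnot(inherits(spec, "spectrogram"))
  S <- spec$mag
  if (ncol(S) < 2) stop("need at least two frames")
  ## loudness-referenced units: clips are compared at equal average level, so
  ## modulation magnitudes do not inherit the arbitrary peak-normalization
  ## gain of the rendered audio (crest factor differs between conditions)
  lev <- sqrt(mean(S^2))
  if (lev > 0) S <- S / lev
  f <- spec$freq
  lo <- max(30, f[2])
  hi <- max(f)
  edges <- exp(seq(log(lo), log(hi), length.out = n_bands + 1))
  band <- findInterval(f, edges, rightmost.closed = TRUE)
  keep <- band >= 1 & band <= n_bands
  env <- rowsum(S[keep, , drop = FALSE], band[keep])  # band x frame envelopes
  env <- env - rowMeans(env)
  nf <- ncol(env)
  nfft <- 2^ceiling(log2(4 * nf))
  padded <- cbind(env, matrix(0, nrow(env), nfft - nf))
  M <- Mod(t(stats::mvfft(t(padded))))                # band x modulation freq
  fm <- (seq_len(nfft) - 1) * spec$frame_rate / nfft
  sel <- fm > 0 & fm <= f_mod_max
  structure(list(freq = fm[sel], mag = colSums(M[, sel, drop = FALSE])),
            class = "fluctuation_spectrum")
}

## parabolic interpolation of a peak position on a uniform grid
interp_peak <- function(freq, mag, idx) {
  if (idx <= 1 || idx >= length(mag)) return(freq[idx])
  y1 <- mag[idx - 1]; y2 <- mag[idx]; y3 <- mag[idx + 1]
  denom <- y1 - 2 * y2 + y3
  if (abs(denom) < 1e-12) return(freq[idx])
  delta <- 0.5 * (y1 - y3) / denom
  freq[idx] + delta * (freq[2] - freq[1])
}

#' Rhythm features from the fluctuation spectrum and onset envelope
#'
#' * `peak_magnitude` - magnitude of the dominant modulation frequency (a.u.)
#' * `peak_to_median` - dominant magnitude relative to the median (salience)
#' * `fluct_entropy` - Shannon entropy of the normalized modulation
#'   distribution divided by `log(bins)` (flatness, in \[0,1\])
#' * `pulse_clarity` - principal non-zero-lag peak of the onset-envelope
#'   autocorrelation, normalized by lag 0
#' * `tempo_bpm` - 60 x the strongest modulation peak in the 30-300 BPM window
#'
#' @param fs a `fluctuation_spectrum`
#' @param spec the `spectrogram` the fluctuation spectrum came from (used for
#'   the onset envelope behind pulse clarity)
#' @param tempo_range_bpm search window for the tempo peak
#' @return named list of the five rhythm features (`NA` with a `flagged`
#'   attribute when the spectrum is all zero)
#' @export
rhythm_features <- function(fs, spec, tempo_range_bpm = c(30, 300)) {
  stopifnot(inherits(fs, "fluctuation_spectrum"), inherits(spec, "spectrogram"))
  mag <- fs$mag
  if (all(mag == 0)) {
    out <- list(peak_magnitude = NA_real_, peak_to_median = NA_real_,
                fluct_entropy = NA_real_, pulse_clarity = NA_real_,
                tempo_bpm = NA_real_)
    attr(out, "flagged") <- "all-zero fluctuation spectrum"
    return(out)
  }
  peak_magnitude <- max(mag)
  med <- stats::median(mag)
  peak_to_median <- if (med > 0) peak_magnitude / med else Inf
  p <- mag / sum(mag)
  nz <- p > 0
  fluct_entropy <- -sum(p[nz] * log(p[nz])) / log(length(p))

  ## tempo: strongest peak in the beat window, parabolic-refined
  win <- fs$freq >= tempo_range_bpm[1] / 60 & fs$freq <= tempo_range_bpm[2] / 60
  tempo_bpm <- NA_real_
  if (any(win)) {
    idx_all <- which(win)
    idx <- idx_all[which.max(mag[idx_all])]
    tempo_bpm <- 60 * interp_peak(fs$freq, mag, idx)
  }

  ## pulse clarity from the spectral-flux onset envelope: the normalized
  ## autocorrelation at the perceived-beat (tactus) lag. Candidate lags are
  ## the local autocorrelation maxima; the tactus is selected with a
  ## log-Gaussian resonance weighting centred on the preferred beat period
  ## (0.5 s), the standard perceptual tempo prior, and the unweighted
  ## correlation at that lag is reported.
  S <- spec$mag
  onset <- c(0, colSums(pmax(S[, -1, drop = FALSE] -
                               S[, -ncol(S), drop = FALSE], 0)))
  max_lag <- min(length(onset) - 1L, as.integer(round(2 * spec$frame_rate)))
  min_lag <- max(1L, as.integer(round(0.2 * spec$frame_rate)))
  pulse_clarity <- NA_real_
  if (max_lag > min_lag && stats::sd(onset) > 0) {
    ac <- stats::acf(onset, lag.max = max_lag, plot = FALSE,
                     demean = TRUE)$acf[, 1, 1]
    r <- ac[-1]                       # r[k] is the correlation at lag k
    loc <- which(diff(sign(diff(r))) < 0) + 1L  # local maxima
    loc <- loc[loc >= min_lag]
    if (length(loc)) {
      tau <- loc / spec$frame_rate
      w <- exp(-log2(tau / 0.5)^2 / (2 * 0.55^2))
      best <- loc[which.max(r[loc] * w)]
      pulse_clarity <- max(0, r[best])
    } else pulse_clarity <- 0
  }
  list(peak_magnitude = peak_magnitude, peak_to_median = peak_to_median,
       fluct_entropy = fluct_entropy, pulse_clarity = pulse_clarity,
       tempo_bpm = tempo_bpm)
}

#' Timbre features
#'
#' * `spectral_flux` - mean over frames of the L2 norm of the positive
#'   difference between consecutive L1-normalized magnitude frames
#' * `rms_dbfs` - `20*log10(RMS)` with digital full scale at 1 (`-Inf` for
#'   silence)
#' * `centroid_hz` - energy-weighted mean frequency, averaged over frames
#'
#' @param clip an `audio_clip`
#' @param spec its `spectrogram`
#' @return named list; `centroid_hz` is `NA` (flagged) for silent input
#' @export
timbre_features <- function(clip, spec) {
  stopifnot(inherits(clip, "audio_clip"), inherits(spec, "spectrogram"))
  S <- spec$mag
  energy <- colSums(S)
  ok <- energy > 0
  rms_val <- rms(clip$samples)
  rms_dbfs <- if (rms_val > 0) 20 * log10(rms_val) else -Inf
  if (!any(ok)) {
    out <- list(spectral_flux = 0, rms_dbfs = rms_dbfs, centroid_hz = NA_real_)
    attr(out, "flagged") <- "silent input: centroid undefined"
    return(out)
  }
  N <- sweep(S[, ok, drop = FALSE], 2, energy[ok], "/")
  flux <- if (ncol(N) > 1) {
    d <- pmax(N[, -1, drop = FALSE] - N[, -ncol(N), drop = FALSE], 0)
    mean(sqrt(colSums(d^2)))
  } else 0
  centroid_hz <- mean(colSums(spec$freq * S[, ok, drop = FALSE]) / energy[ok])
  list(spectral_flux = flux, rms_dbfs = rms_dbfs, centroid_hz = centroid_hz)
}

#' Extract the full feature row for one clip
#'
#' @param clip an `audio_clip`
#' @param window_ms,hop_ms STFT parameters, see [stft_spectrogram()]
#' @return one-row data.frame with the eight rhythm/timbre features plus the
#'   clip label
#' @export
extract_features <- function(clip, window_ms = 46, hop_ms = 10) {
  spec <- stft_spectrogram(clip, window_ms, hop_ms)
  fl <- fluctuation_spectrum(spec)
  rf <- rhythm_features(fl, spec)
  tf <- timbre_features(clip, spec)
  data.frame(label = clip$label, as.data.frame(rf), as.data.frame(tf),
             stringsAsFactors = FALSE)
}

#' Compare features between the two stimulus conditions
#'
#' Per-feature pooled-variance two-sample t-test of chord-progression (CP)
#' versus no-chord-progression (NCP) rows; the t statistic is signed CP - NCP
#' and the degrees of freedom are `n_cp + n_ncp - 2`.
#'
#' @param cp_rows,ncp_rows data.frames of feature rows from
#'   [extract_features()] (numeric columns are compared)
#' @return data.frame with per-condition mean and SD, t, df and p per feature;
#'   features with zero variance in both groups and equal means are flagged
#'   (`NA` statistics)
#' @export
compare_conditions <- function(cp_rows, ncp_rows) {
  stopifnot(nrow(cp_rows) > 0, nrow(ncp_rows) > 0)
  feats <- intersect(names(cp_rows)[vapply(cp_rows, is.numeric, TRUE)],
                     names(ncp_rows)[vapply(ncp_rows, is.numeric, TRUE)])
  out <- lapply(feats, function(f) {
    a <- cp_rows[[f]]; b <- ncp_rows[[f]]
    res <- data.frame(feature = f, mean_cp = mean(a), sd_cp = stats::sd(a),
                      mean_ncp = mean(b), sd_ncp = stats::sd(b),
                      t = NA_real_, df = length(a) + length(b) - 2,
                      p = NA_real_, flagged = FALSE)
    degenerate <- (length(a) < 2 && length(b) < 2) ||
      (isTRUE(all.equal(stats::var(a), 0)) &&
         isTRUE(all.equal(stats::var(b), 0)))
    if (degenerate && isTRUE(all.equal(mean(a), mean(b)))) {
      res$flagged <- TRUE
      return(res)
    }
    tt <- tryCatch(stats::t.test(a, b, var.equal = TRUE),
                   error = function(e) NULL)
    if (is.null(tt)) { res$flagged <- TRUE; return(res) }
    res$t <- unname(tt$statistic)
    res$p <- tt$p.value
    res
  })
  do.call(rbind, out)
}
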