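## Cross-brain wavelet coherence: dyadic scale grid, task-regressor removal,
## complex-Gaussian continuous wavelet transform, per-condition partner
## correlation of coefficient magnitudes, band comparison, and the
## scrambled-pair null.

#' Construct the wavelet scale set
#'
#' Dyadic grid: periods `(1/f_max) * 2^(j/voices)` for
#' `j = 0 .. octaves*voices - 1`, so adjacent periods differ by exactly
#' `2^(1/voices)`. With the defaults (0.4-0.025 Hz, 4 octaves, 4 voices) this
#' yields 16 scales with shortest period 2.5 s. The metadata also records the
#' alternative reading of the grid as 16 periods spanning the two endpoint
#' frequencies inclusively.
#'
#' @param f_max,f_min frequency range in Hz (defaults 0.4 and 0.025)
#' @param octaves,voices octave count and voices per octave (defaults 4, 4)
#' @return a `scale_set` data.frame with `scale` (index) and `period_s`;
#'   attributes `octaves`, `voices`, `f_max`, `f_min`,
#'   `alt_endpoint_periods_s`
#' @export
make_scales <- function(f_max = 0.4, f_min = 0.025, octaves = 4, voices = 4) {
  stopifnot(f_max > f_min, f_min > 0, octaves >= 1, voices >= 1)
  span <- log2(f_max / f_min)
  if (abs(span - octaves) > 1e-8) {
    warning("frequency span (", signif(span, 4), " octaves) differs from ",
            "requested octaves (", octaves, "); the span takes precedence")
    octaves <- span
  }
  n <- as.integer(round(octaves * voices))
  periods <- (1 / f_max) * 2^((seq_len(n) - 1) / voices)
  structure(data.frame(scale = seq_len(n), period_s = periods),
            class = c("scale_set", "data.frame"),
            octaves = octaves, voices = voices, f_max = f_max, f_min = f_min,
            alt_endpoint_periods_s =
              (1 / f_max) * (f_max / f_min)^((seq_len(n) - 1) / (n - 1)))
}

#' Remove the task regressors from a signal
#'
#' OLS residuals of the signal on all task regressors plus intercept, leaving
#' the non-task dynamics whose cross-brain coupling is of interest
#' (psychophysiological-interaction convention).
#'
#' @param y vector or time x channel matrix
#' @param design a `design_matrix`
#' @return residual series, same shape, orthogonal to every design column
#' @export
residualize_task <- function(y, design) {
  Y <- if (is.null(dim(y))) matrix(y, ncol = 1) else as.matrix(y)
  X <- unclass(design)
  if (nrow(Y) != nrow(X)) stop("signal length does not match design")
  ## orthonormal projector (robust to collinear augmented designs)
  sv <- svd(X, nv = 0)
  U <- sv$u[, sv$d > max(sv$d) * 1e-10, drop = FALSE]
  res <- Y - U %*% crossprod(U, Y)
  if (is.null(dim(y))) drop(res) else res
}

#' Augment a design with its detrended self for residualization
#'
#' Preprocessing (wavelet detrending, PCA filtering) removes the slow content
#' of the task regressors from the data, so regressing a *preprocessed*
#' signal on the raw design leaves a task-locked leakage term (the slow part
#' of the regressors) in the residual - which both partners share and which
#' would masquerade as cross-brain coherence. The leakage lies exactly in the
#' span of the raw regressors, their detrended versions and a linear trend,
#' so residualizing on this augmented design removes it.
#'
#' @param design a `design_matrix`
#' @param detrend_cutoff_s the cutoff used during preprocessing (default 128)
#' @return augmented design matrix (keeps the `fs` attribute)
#' @export
augment_design_detrended <- function(design, detrend_cutoff_s = 128) {
  X <- unclass(design)
  fs <- attr(design, "fs")
  conds <- attr(design, "conditions")
  Xd <- wavelet_detrend(X[, conds, drop = FALSE], fs, detrend_cutoff_s)
  out <- cbind(X, Xd, seq_len(nrow(X)) / nrow(X))
  attr(out, "fs") <- fs
  out
}

#' Complex-Gaussian continuous wavelet transform
#'
#' Analytic wavelet with frequency response `(s w)^order exp(-(s w)^2 / 2)` on
#' positive frequencies (a complex Gaussian-derivative kernel, order 4 by
#' default), applied by FFT. The scale for a target period `T` is
#' `s = sqrt(order) * T / (2 pi)` so the response peaks at that period.
#'
#' @param x numeric series (demeaned internally)
#' @param scales a `scale_set`
#' @param fs sampling rate in Hz
#' @param order derivative order of the kernel (default 4)
#' @return a `cwt` object: list with `coef` (time x scale complex matrix),
#'   `period_s`, `fs`, and `coi_s` (per-scale e-folding time in seconds used
#'   for edge masking)
#' @export
cwt_complex <- function(x, scales, fs, order = 4) {
  stopifnot(inherits(scales, "scale_set"), fs > 0)
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2 * max(scales$period_s) * fs) {
    stop("series too short: need at least twice the longest period")
  }
  x <- x - mean(x)
  N <- 2^ceiling(log2(n))
  xh <- stats::fft(c(x, numeric(N - n)))
  w <- 2 * pi * fs * (seq_len(N) - 1) / N           # angular freq, wrap later
  pos <- seq_len(N) - 1 <= N / 2                    # analytic: positive only
  coef <- matrix(complex(real = 0), n, nrow(scales))
  s_sec <- sqrt(order) * scales$period_s / (2 * pi)
  ## kernels are peak-normalized in frequency so a unit sinusoid elicits the
  ## same maximal response at every scale (the ridge falls on the nearest
  ## scale, and correlations are unaffected by per-scale gain anyway)
  peak_gain <- order^(order / 2) * exp(-order / 2)
  for (j in seq_len(nrow(scales))) {
    psi <- numeric(N)
    sw <- s_sec[j] * w[pos]
    psi[pos] <- (sw^order) * exp(-sw^2 / 2) / peak_gain
    W <- stats::fft(xh * psi, inverse = TRUE) / N
    coef[, j] <- W[seq_len(n)]
  }
  structure(list(coef = coef, period_s = scales$period_s, fs = fs,
                 coi_s = sqrt(2) * s_sec),
            class = "cwt")
}

## per-scale validity mask: condition samples, excluding one e-folding at the
## edges of the transformed series
coherence_mask <- function(cw, paradigm, condition) {
  n <- nrow(cw$coef)
  base <- condition_mask(paradigm, condition, cw$fs, n)
  lapply(seq_along(cw$period_s), function(j) {
    m <- as.integer(ceiling(cw$coi_s[j] * cw$fs))
    edge <- rep(TRUE, n)
    if (m > 0) {
      edge[seq_len(min(m, n))] <- FALSE
      edge[seq.int(max(1L, n - m + 1L), n)] <- FALSE
    }
    base & edge
  })
}

#' Cross-brain coherence between two participants' wavelet coefficients
#'
#' Per scale, the Pearson correlation between the partners' coefficient
#' magnitude series over the concatenated samples of the given condition's
#' blocks (cone-of-influence samples at the series edges excluded).
#'
#' @param cwt_a,cwt_b `cwt` objects for the two partners (same channel role),
#'   aligned in time
#' @param paradigm the `paradigm` the recordings followed
#' @param condition condition whose blocks are analysed
#' @param statistic `"magnitude"` (default) correlates coefficient moduli;
#'   `"real"` correlates real parts
#' @return data.frame with `period_s`, `coherence` (in \[-1,1\], `NA` flagged
#'   when no valid samples remain) and `n_samples`
#' @export
cross_brain_coherence <- function(cwt_a, cwt_b, paradigm, condition,
                                  statistic = c("magnitude", "real")) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(cwt_a, "cwt"), inherits(cwt_b, "cwt"))
  if (!identical(dim(cwt_a$coef), dim(cwt_b$coef))) {
    stop("coefficient arrays are not aligned")
  }
  if (!condition %in% paradigm$condition) {
    stop("condition '", condition, "' not present in paradigm")
  }
  masks <- coherence_mask(cwt_a, paradigm, condition)
  out <- data.frame(period_s = cwt_a$period_s, coherence = NA_real_,
                    n_samples = 0L)
  for (j in seq_along(masks)) {
    idx <- masks[[j]]
    if (sum(idx) < 3) next
    a <- cwt_a$coef[idx, j]; b <- cwt_b$coef[idx, j]
    va <- if (statistic == "magnitude") Mod(a) else Re(a)
    vb <- if (statistic == "magnitude") Mod(b) else Re(b)
    if (stats::sd(va) == 0 || stats::sd(vb) == 0) next
    out$coherence[j] <- stats::cor(va, vb)
    out$n_samples[j] <- sum(idx)
  }
  out
}

#' Dyad-level coherence spectrum over channel pairs and conditions
#'
#' Convenience wrapper running the full single-dyad coherence pipeline:
#' task-regressor removal on both partners' signals, complex-Gaussian CWT of
#' the designated channels, and per-condition cross-brain correlation for
#' each channel pair.
#'
#' @param hb_a,hb_b time x channel HbDiff matrices for partners A and B
#' @param design the `design_matrix` used for residualization
#' @param paradigm the `paradigm`
#' @param pairs data.frame with `channel_a`, `channel_b`
#' @param scales a `scale_set` (default [make_scales()])
#' @param conditions conditions to analyse (default the four task conditions)
#' @param dyad_id identifier copied to the output
#' @param detrend_cutoff_s preprocessing detrend cutoff, used to augment the
#'   residualization design (see [augment_design_detrended()]); `NULL` uses
#'   the raw design only
#' @return a `coherence_spectrum` data.frame: `dyad`, `channel_a`,
#'   `channel_b`, `condition`, `period_s`, `coherence`, `n_samples`
#' @export
coherence_spectrum <- function(hb_a, hb_b, design, paradigm, pairs,
                               scales = make_scales(),
                               conditions = TASK_CONDITIONS, dyad_id = 1,
                               detrend_cutoff_s = 128) {
  fs <- attr(design, "fs")
  Xr <- if (is.null(detrend_cutoff_s)) design else
    augment_design_detrended(design, detrend_cutoff_s)
  ra <- residualize_task(hb_a, Xr)
  rb <- residualize_task(hb_b, Xr)
  need_a <- unique(pairs$channel_a)
  need_b <- unique(pairs$channel_b)
  cwa <- lapply(need_a, function(ch) cwt_complex(ra[, ch], scales, fs))
  names(cwa) <- as.character(need_a)
  cwb <- lapply(need_b, function(ch) cwt_complex(rb[, ch], scales, fs))
  names(cwb) <- as.character(need_b)
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    for (cond in conditions) {
      r <- cross_brain_coherence(cwa[[as.character(pairs$channel_a[i])]],
                                 cwb[[as.character(pairs$channel_b[i])]],
                                 paradigm, cond)
      rows[[length(rows) + 1L]] <- data.frame(
        dyad = dyad_id, channel_a = pairs$channel_a[i],
        channel_b = pairs$channel_b[i], condition = cond, r)
    }
  }
  structure(do.call(rbind, rows),
            class = c("coherence_spectrum", "data.frame"))
}

#' @export
plot.coherence_spectrum <- function(x, ...) {
  agg <- stats::aggregate(coherence ~ period_s + condition, data = x, FUN = mean)
  conds <- unique(agg$condition)
  cols <- seq_along(conds)
  graphics::matplot(
    x = unique(sort(agg$period_s)),
    y = sapply(conds, function(cc) {
      sub <- agg[agg$condition == cc, ]
      sub$coherence[order(sub$period_s)]
    }),
    type = "l", lty = 1, col = cols, xlab = "period (s)",
    ylab = "cross-brain coherence", ...)
  graphics::legend("topleft", legend = conds, col = cols, lty = 1, bty = "n")
  invisible(x)
}

#' Compare band-mean coherence between two conditions
#'
#' Per dyad, the mean coherence over all scales with period inside the band
#' (and over channel pairs), followed by a paired t-test across dyads.
#'
#' @param spectra a `coherence_spectrum` (possibly row-bound over dyads)
#' @param band period band in seconds, default `c(10, 20)`
#' @param cond_a,cond_b the two conditions (pairing unit: dyad)
#' @return list with `t`, `df`, `p`, `mean_diff` (cond_a - cond_b), `n_dyads`,
#'   `band`
#' @export
band_compare <- function(spectra, band = c(10, 20), cond_a = "face_chord",
                         cond_b = "face_nochord") {
  sub <- spectra[spectra$period_s >= band[1] & spectra$period_s <= band[2] &
                   spectra$condition %in% c(cond_a, cond_b) &
                   !is.na(spectra$coherence), , drop = FALSE]
  if (!nrow(sub)) stop("band contains no scales")
  agg <- stats::aggregate(coherence ~ dyad + condition, data = sub, FUN = mean)
  wa <- agg[agg$condition == cond_a, c("dyad", "coherence")]
  wb <- agg[agg$condition == cond_b, c("dyad", "coherence")]
  merged <- merge(wa, wb, by = "dyad", suffixes = c("_a", "_b"))
  if (nrow(merged) < 3) stop("need at least 3 dyads with both conditions")
  d <- merged$coherence_a - merged$coherence_b
  if (stats::sd(d) == 0) {
    return(list(t = 0, df = nrow(merged) - 1, p = 1, mean_diff = mean(d),
                n_dyads = nrow(merged), band = band))
  }
  tt <- stats::t.test(merged$coherence_a, merged$coherence_b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_diff = mean(d), n_dyads = nrow(merged), band = band)
}

## sample a derangement (permutation without fixed points) of 1..n
sample_derangement <- function(n) {
  if (n < 2) stop("need at least 2 dyads to scramble")
  repeat {
    p <- sample.int(n)
    if (!any(p == seq_len(n))) return(p)
  }
}

#' Scrambled-pair null coherence
#'
#' Pairs participant A of each dyad with participant B of a different dyad
#' (derangement sampling) and runs the identical coherence pipeline, aligning
#' the partner's data to dyad A's paradigm. The distribution of the resulting
#' spectra is the null against which true-pair coherence is judged.
#'
#' @param hb_a_list,hb_b_list lists (one element per dyad) of time x channel
#'   HbDiff matrices for the A and B participants
#' @param design_list list of `design_matrix` objects per dyad
#' @param paradigm_list list of `paradigm` objects per dyad
#' @param pairs channel-pair data.frame as in [coherence_spectrum()]
#' @param rng_seed seed for the derangement draws
#' @param n_draws number of scrambled pairings (0 gives an empty collection)
#' @param ... passed to [coherence_spectrum()]
#' @return a `coherence_spectrum` with an extra `draw` column
#' @export
scrambled_pairs <- function(hb_a_list, hb_b_list, design_list, paradigm_list,
                            pairs, rng_seed = 1, n_draws = 1, ...) {
  n <- length(hb_a_list)
  if (n < 2) stop("need at least 2 dyads to scramble")
  if (n_draws == 0) {
    out <- data.frame(draw = integer(0), dyad = integer(0),
                      channel_a = integer(0), channel_b = integer(0),
                      condition = character(0), period_s = numeric(0),
                      coherence = numeric(0), n_samples = integer(0))
    return(structure(out, class = c("coherence_spectrum", "data.frame")))
  }
  perms <- with_seed(rng_seed,
                     lapply(seq_len(n_draws), function(d) sample_derangement(n)))
  rows <- list()
  for (d in seq_len(n_draws)) {
    perm <- perms[[d]]
    for (i in seq_len(n)) {
      sp <- coherence_spectrum(hb_a_list[[i]], hb_b_list[[perm[i]]],
                               design_list[[i]], paradigm_list[[i]], pairs,
                               dyad_id = i, ...)
      rows[[length(rows) + 1L]] <- data.frame(draw = d, sp)
    }
  }
  structure(do.call(rbind, rows), class = c("coherence_spectrum", "data.frame"))
}
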