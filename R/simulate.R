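## Synthetic dyadic fNIRS: paradigm builder and a forward model producing raw
## three-wavelength optical-density recordings with known ground truth
## (HRF-convolved block responses, systemic globals, channel noise, and a
## band-limited cross-brain coupled component gated to specified conditions).

TASK_CONDITIONS <- c("face_chord", "face_nochord", "noface_chord",
                     "noface_nochord")

#' Build the block paradigm
#'
#' Each run contains each of the four conditions exactly once as a 15 s task
#' block followed by a 15 s rest block; the condition order is shuffled per
#' run from `order_seed`. Eight runs give the 16 min session.
#'
#' @param n_runs number of runs (default 8)
#' @param task_s,rest_s task and rest block durations in seconds (default 15)
#' @param order_seed seed for the per-run condition order
#' @return a `paradigm` data.frame with columns `run`, `onset_s`,
#'   `duration_s`, `condition` (task conditions plus `"rest"`) and attributes
#'   `n_runs`, `run_length_s`, `total_s`
#' @export
make_paradigm <- function(n_runs = 8, task_s = 15, rest_s = 15,
                          order_seed = 1) {
  stopifnot(n_runs >= 1, task_s > 0, rest_s >= 0)
  run_length <- 4 * (task_s + rest_s)
  rows <- list()
  for (r in seq_len(n_runs)) {
    ord <- with_seed(derive_seed(order_seed, paste0("run_order_", r)),
                     sample(TASK_CONDITIONS))
    for (i in seq_len(4)) {
      base <- (r - 1) * run_length + (i - 1) * (task_s + rest_s)
      rows[[length(rows) + 1L]] <-
        data.frame(run = r, onset_s = base, duration_s = task_s,
                   condition = ord[i])
      rows[[length(rows) + 1L]] <-
        data.frame(run = r, onset_s = base + task_s, duration_s = rest_s,
                   condition = "rest")
    }
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("paradigm", "data.frame"),
            n_runs = n_runs, run_length_s = run_length, task_s = task_s,
            rest_s = rest_s, total_s = n_runs * run_length)
}

#' Default simulation ground truth
#'
#' Condition amplitudes follow the study's expected ordering: the live
#' face + chord-progression response is 1.0 (a.u.) and the other three
#' conditions 0.5, on twelve "signal" channels whose gains vary across the
#' scalp; the remaining channels carry no task response. Cross-brain coupling
#' (strength 0.6 at a 15 s period) is injected only during face_chord blocks
#' on three designated channel pairs. Systemic globals are cardiac (1 Hz),
#' respiratory (0.25 Hz) and Mayer-wave (0.1 Hz) sinusoids plus random-walk
#' drift, shared across channels within a participant.
#'
#' @param n_channels channels per participant (default 29, the acquisition
#'   montage size)
#' @param noise_sd white channel-noise SD (a.u.)
#' @return a `dyad_truth` list
#' @export
default_ground_truth <- function(n_channels = 29, noise_sd = 0.2) {
  active <- seq_len(min(12L, n_channels))
  gain <- seq(0.6, 1.4, length.out = length(active))
  cond_amp <- c(face_chord = 1.0, face_nochord = 0.5, noface_chord = 0.5,
                noface_nochord = 0.5)
  beta <- array(0, dim = c(2, n_channels, 4),
                dimnames = list(c("a", "b"), NULL, TASK_CONDITIONS))
  for (p in 1:2) {
    g <- if (p == 1) gain else rev(gain)
    for (cond in TASK_CONDITIONS) beta[p, active, cond] <- g * cond_amp[[cond]]
  }
  coupling <- data.frame(channel_a = c(5L, 12L, 20L),
                         channel_b = c(5L, 17L, 8L),
                         period_s = 15, strength = 0.6,
                         condition = "face_chord")
  coupling <- coupling[coupling$channel_a <= n_channels &
                         coupling$channel_b <= n_channels, , drop = FALSE]
  structure(list(
    n_channels = n_channels,
    beta_true = beta,
    coupling = coupling,
    coupled_amp = 0.3,
    noise_sd = noise_sd,
    globals = list(cardiac = c(freq = 1.0, amp = 0.3),
                   respiratory = c(freq = 0.25, amp = 0.2),
                   mayer = c(freq = 0.1, amp = 0.2)),
    drift_sd = 0.005,
    gamma = 1 / 3
  ), class = "dyad_truth")
}

#' Nominal extinction coefficients
#'
#' A 3 (wavelength: 780, 805, 830 nm) x 2 (chromophore: HbO, HbR) matrix of
#' nominal molar extinction coefficients (1/(mM cm)) in the range of standard
#' published compilations; 805 nm sits near the isosbestic point. Absolute
#' calibration is irrelevant here because concentrations are expressed in
#' relative units with unit pathlength.
#'
#' @return named 3x2 numeric matrix
#' @export
default_extinction <- function() {
  matrix(c(0.735, 1.030,
           0.870, 0.820,
           1.070, 0.780),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("780", "805", "830"), c("HbO", "HbR")))
}

#' Forward (modified) Beer-Lambert mapping
#'
#' Maps chromophore concentration changes to optical-density changes per
#' wavelength: `od(lambda, t) = eps(lambda, HbO) oxy(t) + eps(lambda, HbR)
#' deoxy(t)` with unit pathlength.
#'
#' @param oxy,deoxy numeric vectors (or time x channel matrices) of equal shape
#' @param extinction 3x2 extinction matrix, see [default_extinction()]
#' @return a list of od series per wavelength (same shape as the inputs),
#'   named by wavelength
#' @export
forward_beer_lambert <- function(oxy, deoxy, extinction = default_extinction()) {
  if (!identical(dim(oxy) %||% length(oxy), dim(deoxy) %||% length(deoxy))) {
    stop("oxy and deoxy must have the same shape")
  }
  if (kappa(extinction, exact = TRUE) > 1e6) {
    stop("extinction matrix is ill-conditioned (condition number > 1e6)")
  }
  out <- lapply(seq_len(nrow(extinction)), function(l) {
    extinction[l, 1] * oxy + extinction[l, 2] * deoxy
  })
  names(out) <- rownames(extinction)
  out
}

## band-limited unit-variance Gaussian process centred at 1/period_s Hz
bandlimited_noise <- function(n, fs, period_s, rel_bw = 1 / 6) {
  f0 <- 1 / period_s
  white <- stats::rnorm(n)
  X <- stats::fft(white)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                      # two-sided frequency magnitude
  H <- exp(-((f - f0)^2) / (2 * (rel_bw * f0)^2))
  x <- Re(stats::fft(X * H, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

condition_mask <- function(paradigm, condition, fs, n) {
  mask <- logical(n)
  blocks <- paradigm[paradigm$condition == condition, , drop = FALSE]
  for (i in seq_len(nrow(blocks))) {
    i0 <- floor(blocks$onset_s[i] * fs) + 1L
    i1 <- min(n, ceiling((blocks$onset_s[i] + blocks$duration_s[i]) * fs))
    if (i1 >= i0) mask[i0:i1] <- TRUE
  }
  mask
}

#' Simulate one dyad
#'
#' Forward model per channel:
#' `OxyHb(t) = sum_c beta_true * (boxcar_c (*) HRF) + global(t) + coupled(t)
#' + noise`, with `deOxyHb = -gamma * (task + coupled) + own globals + noise`.
#' The coupled component is a band-limited Gaussian process at the specified
#' period, mixed into both partners' designated channels only during the
#' designated condition blocks, with partner correlation equal to the coupling
#' strength. Chromophores are mapped to three-wavelength optical density by
#' the forward Beer-Lambert matrix.
#'
#' @param paradigm a `paradigm` from [make_paradigm()]
#' @param truth a `dyad_truth` from [default_ground_truth()]
#' @param rng_seed integer seed; all randomness flows from it
#' @param fs sampling rate in Hz (default 30)
#' @param extinction forward extinction matrix
#' @param dyad_id identifier stored in the recordings
#' @return a `dyad_recording`: list with participant recordings `a` and `b`
#'   (each an `fnirs_recording` holding the time x channel x wavelength od
#'   array), the `truth`, the `paradigm` and the seed
#' @export
simulate_dyad <- function(paradigm, truth = default_ground_truth(),
                          rng_seed = 1, fs = 30,
                          extinction = default_extinction(), dyad_id = 1) {
  stopifnot(inherits(paradigm, "paradigm"), inherits(truth, "dyad_truth"))
  nch <- truth$n_channels
  if (dim(truth$beta_true)[2] != nch) stop("beta_true/channel mismatch")
  if (nrow(truth$coupling) &&
      (max(truth$coupling$channel_a, truth$coupling$channel_b) > nch ||
       min(truth$coupling$channel_a, truth$coupling$channel_b) < 1)) {
    stop("coupling channels out of range 1..", nch)
  }
  n <- as.integer(round(attr(paradigm, "total_s") * fs))
  hrf <- canonical_hrf(1 / fs)
  X <- build_design(paradigm, hrf = hrf, fs = fs)
  Xc <- X[, TASK_CONDITIONS, drop = FALSE]

  make_globals <- function() {
    t <- (seq_len(n) - 1) / fs
    g <- numeric(n)
    for (comp in truth$globals) {
      g <- g + comp[["amp"]] * sin(2 * pi * comp[["freq"]] * t +
                                     stats::runif(1, 0, 2 * pi))
    }
    g + cumsum(stats::rnorm(n, 0, truth$drift_sd))
  }

  result <- with_seed(rng_seed, {
    ## shared coupled processes, one per coupling row
    shared <- lapply(seq_len(nrow(truth$coupling)), function(i) {
      bandlimited_noise(n, fs, truth$coupling$period_s[i])
    })
    recs <- list()
    for (p in 1:2) {
      task <- Xc %*% t(truth$beta_true[p, , , drop = TRUE][, TASK_CONDITIONS])
      coupled <- matrix(0, n, nch)
      for (i in seq_len(nrow(truth$coupling))) {
        cp <- truth$coupling[i, ]
        ch <- if (p == 1) cp$channel_a else cp$channel_b
        own <- bandlimited_noise(n, fs, cp$period_s)
        mixed <- sqrt(cp$strength) * shared[[i]] +
          sqrt(1 - cp$strength) * own
        mask <- condition_mask(paradigm, cp$condition, fs, n)
        coupled[, ch] <- coupled[, ch] + truth$coupled_amp * mixed * mask
      }
      g_oxy <- make_globals()
      g_deoxy <- make_globals()
      oxy <- task + coupled + g_oxy +
        matrix(stats::rnorm(n * nch, 0, truth$noise_sd), n, nch)
      deoxy <- -truth$gamma * (task + coupled) + g_deoxy +
        matrix(stats::rnorm(n * nch, 0, truth$noise_sd), n, nch)
      od <- forward_beer_lambert(oxy, deoxy, extinction)
      od_arr <- array(NA_real_, dim = c(n, nch, 3),
                      dimnames = list(NULL, NULL, rownames(extinction)))
      for (l in 1:3) od_arr[, , l] <- od[[l]]
      recs[[p]] <- structure(
        list(od = od_arr, sample_rate = fs,
             participant_id = c("a", "b")[p], dyad_id = dyad_id),
        class = "fnirs_recording")
    }
    recs
  })

  structure(list(a = result[[1]], b = result[[2]], truth = truth,
                 paradigm = paradigm, seed = rng_seed, dyad_id = dyad_id),
            class = "dyad_recording")
}

#' @export
print.fnirs_recording <- function(x, ...) {
  d <- dim(x$od)
  cat(sprintf(
    "<fnirs_recording> participant %s (dyad %s): %d samples x %d channels x %d wavelengths at %g Hz\n",
    x$participant_id, x$dyad_id, d[1], d[2], d[3], x$sample_rate))
  invisible(x)
}

#' @export
print.dyad_recording <- function(x, ...) {
  cat(sprintf("<dyad_recording> dyad %s (seed %d)\n", x$dyad_id, x$seed))
  print(x$a); print(x$b)
  invisible(x)
}
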