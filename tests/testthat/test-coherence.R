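test_that("the default scale grid has 16 dyadically spaced scales from 2.5 s", {
  sc <- make_scales()
  expect_equal(nrow(sc), 16)
  expect_equal(min(sc$period_s), 2.5)
  ratios <- sc$period_s[-1] / sc$period_s[-16]
  expect_equal(ratios, rep(2^(1 / 4), 15), tolerance = 1e-12)
  ## the endpoint-spanning alternative grid is carried in metadata
  alt <- attr(sc, "alt_endpoint_periods_s")
  expect_equal(range(alt), c(2.5, 40))
  expect_equal(nrow(make_scales(octaves = 1, voices = 1,
                                f_min = 0.2, f_max = 0.4)), 1)
  expect_warning(make_scales(f_min = 0.05), "span")
})

test_that("residualization annihilates task signals and passes orthogonal ones", {
  p <- tiny_paradigm()
  X <- build_design(p, fs = 30)
  task <- X[, "face_chord"]
  expect_lt(sqrt(mean(residualize_task(task, X)^2)), 1e-8)
  set.seed(2)
  noise <- rnorm(nrow(X))
  ortho <- residualize_task(noise, X)
  expect_gt(stats::cor(ortho, noise), 0.99)
  ## residuals orthogonal to every design column
  expect_lt(max(abs(crossprod(unclass(X), residualize_task(noise, X)))), 1e-6)
})

test_that("the CWT is linear, analytic, and ridges at the stimulus period", {
  sc <- make_scales()
  fs <- 2
  n <- 400
  x <- sin(2 * pi * (1:n) / (15 * fs))           # 15 s period
  cw <- cwt_complex(x, sc, fs)
  power <- colMeans(Mod(cw$coef)^2)
  expect_equal(cw$period_s[which.max(power)],
               sc$period_s[which.min(abs(sc$period_s - 15))])
  expect_equal(Mod(cwt_complex(2 * x, sc, fs)$coef), 2 * Mod(cw$coef),
               tolerance = 1e-9)
  expect_equal(max(Mod(cwt_complex(numeric(n), sc, fs)$coef)), 0)
  expect_error(cwt_complex(numeric(50), sc, fs), "too short")
})

test_that("coherence is 1 for identical partners and symmetric under swap", {
  p <- tiny_paradigm()
  sc <- make_scales()
  set.seed(4)
  x <- rnorm(120 * 30)
  y <- rnorm(120 * 30)
  ca <- cwt_complex(x, sc, 30)
  cb <- cwt_complex(y, sc, 30)
  self <- cross_brain_coherence(ca, ca, p, "face_chord")
  expect_true(all(abs(self$coherence[!is.na(self$coherence)] - 1) < 1e-12))
  ab <- cross_brain_coherence(ca, cb, p, "face_chord")
  ba <- cross_brain_coherence(cb, ca, p, "face_chord")
  expect_equal(ab$coherence, ba$coherence, tolerance = 1e-12)
  expect_error(cross_brain_coherence(ca, cb, p, "nonexistent"), "condition")
})

test_that("independent partners give null-centered coherence", {
  p <- tiny_paradigm()
  sc <- make_scales()
  set.seed(6)
  vals <- replicate(12, {
    ca <- cwt_complex(rnorm(120 * 30), sc, 30)
    cb <- cwt_complex(rnorm(120 * 30), sc, 30)
    r <- cross_brain_coherence(ca, cb, p, "face_chord")
    mean(r$coherence, na.rm = TRUE)
  })
  expect_lt(abs(mean(vals)), 3 * sd(vals) / sqrt(length(vals)))
})

test_that("band comparison matches the paired-t oracle", {
  ## 5 dyads, hand-made paired values
  a_vals <- c(0.5, 0.6, 0.4, 0.7, 0.55)
  b_vals <- c(0.3, 0.45, 0.35, 0.5, 0.4)
  rows <- do.call(rbind, lapply(1:5, function(d) {
    data.frame(dyad = d, channel_a = 1, channel_b = 1,
               condition = rep(c("face_chord", "face_nochord"), each = 1),
               period_s = 15, coherence = c(a_vals[d], b_vals[d]),
               n_samples = 100)
  }))
  out <- band_compare(rows)
  d <- a_vals - b_vals
  t_oracle <- mean(d) / (sd(d) / sqrt(5))        # closed-form paired t
  expect_equal(out$t, t_oracle, tolerance = 1e-12)
  expect_equal(out$df, 4)
  ## identical conditions: t = 0, p = 1
  same <- rows
  same$coherence <- rep(a_vals, each = 2)
  out0 <- band_compare(same)
  expect_equal(out0$t, 0)
  expect_equal(out0$p, 1)
  outside <- rows
  outside$period_s <- 5
  expect_error(band_compare(outside), "band")
})

test_that("scrambled pairings are deranged, reproducible, and empty for 0 draws", {
  set.seed(1)
  for (i in 1:20) {
    perm <- dyadtune:::sample_derangement(6)
    expect_true(all(perm != 1:6))
    expect_setequal(perm, 1:6)
  }
  expect_error(dyadtune:::sample_derangement(1), "at least 2")
  p <- tiny_paradigm()
  X <- build_design(p, fs = 30)
  set.seed(9)
  hb <- lapply(1:3, function(i) matrix(rnorm(120 * 30 * 2), ncol = 2))
  hb2 <- lapply(1:3, function(i) matrix(rnorm(120 * 30 * 2), ncol = 2))
  pairs <- data.frame(channel_a = 1, channel_b = 2)
  args <- list(hb, hb2, list(X, X, X), list(p, p, p), pairs,
               detrend_cutoff_s = NULL)
  s1 <- do.call(scrambled_pairs, c(args, rng_seed = 5, n_draws = 2))
  s2 <- do.call(scrambled_pairs, c(args, rng_seed = 5, n_draws = 2))
  expect_identical(s1, s2)
  expect_equal(sort(unique(s1$draw)), 1:2)
  s0 <- do.call(scrambled_pairs, c(args, rng_seed = 5, n_draws = 0))
  expect_equal(nrow(s0), 0)
  expect_error(scrambled_pairs(hb[1], hb2[1], list(X), list(p), pairs),
               "at least 2")
})

test_that("coupling survives residualization while task coherence does not", {
  ## task-only signals: residualization leaves nothing coherent in-band
  p <- tiny_paradigm()
  tr_task <- tiny_truth(n_channels = 2, noise_sd = 0.05)
  X <- build_design(p, fs = 30)
  pairs <- data.frame(channel_a = 1, channel_b = 1)
  set.seed(31)
  vals <- sapply(1:6, function(i) {
    dy <- simulate_dyad(p, tr_task, rng_seed = 40 + i)
    ha <- mbll_invert(dy$a); hb <- mbll_invert(dy$b)
    sp <- coherence_spectrum(ha$oxy - ha$deoxy, hb$oxy - hb$deoxy, X, p,
                             pairs, detrend_cutoff_s = NULL)
    mean(sp$coherence[sp$condition == "face_chord" &
                        sp$period_s >= 10 & sp$period_s <= 20], na.rm = TRUE)
  })
  expect_lt(abs(mean(vals)), 3 * sd(vals) / sqrt(length(vals)) + 0.05)
  ## coupled process: survives residualization with high fidelity
  tr_cpl <- tiny_truth(n_channels = 2, noise_sd = 0, coupling = TRUE,
                       strength = 1)
  tr_cpl$beta_true[, 1, ] <- 1        # task on the coupled channel too
  dy <- simulate_dyad(p, tr_cpl, rng_seed = 77)
  ha <- mbll_invert(dy$a)
  res <- residualize_task(ha$oxy[, 1] - ha$deoxy[, 1], X)
  ## reconstruct the injected gated process for comparison
  dy0 <- simulate_dyad(p, {
    t0 <- tr_cpl; t0$beta_true[] <- 0; t0
  }, rng_seed = 77)
  injected <- mbll_invert(dy0$a)$oxy[, 1]
  expect_gt(stats::cor(res, injected), 0.9)
})
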