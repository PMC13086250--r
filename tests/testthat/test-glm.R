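test_that("the canonical HRF peaks at 6 s and refines consistently", {
  for (dt in c(0.1, 1 / 30)) {
    h <- canonical_hrf(dt)
    expect_lt(abs((which.max(h) - 1) * dt - 6), dt + 1e-12)
    expect_gt(sum(h) * dt, 0)
    expect_equal(max(h), 1)
  }
  ## halving dt leaves the shape invariant after interpolation
  h1 <- canonical_hrf(0.1)
  h2 <- canonical_hrf(0.05)
  t1 <- seq(0, 32, by = 0.1)
  interp <- stats::approx(seq(0, 32, by = 0.05), h2, xout = t1)$y
  expect_lt(max(abs(h1 - interp)), 1e-3)
})

test_that("design construction covers the paradigm and rejects overlap", {
  p <- tiny_paradigm()
  X <- build_design(p, fs = 30)
  expect_equal(ncol(X), 5)  # four conditions + intercept
  expect_equal(nrow(X), 120 * 30)
  ## one 15 s block: regressor support is block + kernel length
  one <- structure(data.frame(run = 1, onset_s = 0, duration_s = 15,
                              condition = "face_chord"),
                   class = c("paradigm", "data.frame"), total_s = 120)
  X1 <- build_design(one, fs = 10)
  supp <- sum(abs(X1[, "face_chord"]) > 1e-6 * max(X1[, "face_chord"])) / 10
  expect_lt(abs(supp - (15 + 32)), 2)
  ## empty paradigm: intercept-only
  empty <- structure(data.frame(run = integer(0), onset_s = numeric(0),
                                duration_s = numeric(0),
                                condition = character(0)),
                     class = c("paradigm", "data.frame"), total_s = 10)
  expect_equal(colnames(build_design(empty, fs = 10)), "(intercept)")
  bad <- structure(data.frame(run = 1, onset_s = c(0, 5), duration_s = c(10, 10),
                              condition = c("face_chord", "face_nochord")),
                   class = c("paradigm", "data.frame"), total_s = 30)
  expect_error(build_design(bad, fs = 10), "overlap")
})

test_that("OLS recovers exact coefficients and matches the normal-equations oracle", {
  p <- tiny_paradigm()
  X <- build_design(p, fs = 30)
  y <- 2 * X[, "face_chord"]
  fit <- fit_glm(y, X)
  b <- coef(fit)[, 1]
  expect_equal(unname(b["face_chord"]), 2, tolerance = 1e-8)
  expect_lt(max(abs(b[setdiff(names(b), "face_chord")])), 1e-8)
  ## random small designs vs solve(X'X, X'y)
  set.seed(5)
  for (i in 1:5) {
    Xs <- cbind(rnorm(20), rnorm(20), 1)
    attr(Xs, "conditions") <- c("a", "b")
    ys <- rnorm(20)
    oracle <- solve(t(Xs) %*% Xs, t(Xs) %*% ys)
    expect_equal(unname(coef(fit_glm(ys, Xs))[, 1]), c(oracle),
                 tolerance = 1e-8)
  }
  expect_error(fit_glm(rnorm(10), X), "length")
})

test_that("pure-noise betas are centered at zero", {
  set.seed(8)
  n <- 200
  X <- cbind(box = rep(c(0, 1), each = n / 2), 1)
  attr(X, "conditions") <- "box"
  sims <- replicate(1000, coef(fit_glm(rnorm(n), X))[1, 1])
  se <- sd(sims) / sqrt(length(sims))
  expect_lt(abs(mean(sims)), 3 * se)
})

test_that("group contrasts are linear and flag degenerate channels", {
  set.seed(13)
  betas <- array(rnorm(10 * 3 * 2, mean = rep(c(1, 0.4), each = 30)),
                 dim = c(10, 3, 2),
                 dimnames = list(NULL, NULL, c("face_chord", "face_nochord")))
  ct <- group_contrast(betas, c(face_chord = 1, face_nochord = -1))
  ct_neg <- group_contrast(betas, c(face_chord = -1, face_nochord = 1))
  expect_equal(ct_neg$t, -ct$t)
  ct_scaled <- group_contrast(betas, c(face_chord = 2, face_nochord = -2))
  expect_equal(ct_scaled$t, ct$t)                 # scale-invariant t
  expect_equal(ct$df, rep(9, 3))
  degenerate <- betas
  degenerate[, 1, ] <- rep(c(2, 1), each = 10)    # identical contrast values
  expect_true(group_contrast(degenerate,
                             c(face_chord = 1, face_nochord = -1))$flagged[1])
  expect_error(group_contrast(betas[1:2, , , drop = FALSE],
                              c(face_chord = 1)), "participants")
})

test_that("ratings covariates recover constructed associations", {
  set.seed(17)
  np <- 24
  signs <- 0
  for (rep in 1:20) {
    cov_true <- rnorm(np, 3, 1)
    betas <- array(NA_real_, c(np, 2, 2),
                   dimnames = list(as.character(1:np), NULL,
                                   c("face_chord", "face_nochord")))
    betas[, , "face_chord"] <- 0.8 * cov_true + rnorm(np * 2, 0, 0.3)
    betas[, , "face_nochord"] <- rnorm(np * 2, 0, 0.3)
    ratings <- data.frame(participant = rep(1:np, each = 2),
                          condition = rep(c("face_chord", "face_nochord"), np),
                          rating = pmax(1, pmin(5, round(
                            rep(cov_true, each = 2) +
                              c(0, -1) + rnorm(2 * np, 0, 0.2)))))
    ca <- covariate_association(betas, ratings, c(face_chord = 1))
    signs <- signs + all(ca$slope > 0)
  }
  expect_gte(signs / 20, 0.95)
  ## degenerate inputs
  betas1 <- array(1, c(1, 2, 1), dimnames = list("1", NULL, "face_chord"))
  expect_error(covariate_association(betas1, data.frame(), c(face_chord = 1)),
               "participants")
})
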