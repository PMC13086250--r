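## Block-design GLM: canonical double-gamma HRF, design construction,
## per-channel OLS, group contrasts and the ratings-as-covariate association.

#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities parameterised by their modes: the
#' response gamma peaks at `peak_s` (shape `peak_s + 1`, rate 1) and the
#' undershoot gamma at `undershoot_s`, scaled by `1/ratio`. The kernel spans
#' `duration_s` seconds and is normalized to unit peak.
#'
#' @param dt_s sampling interval in seconds (> 0)
#' @param peak_s response peak time (default 6 s)
#' @param undershoot_s undershoot peak time (default 16 s)
#' @param ratio peak-to-undershoot amplitude ratio (default 6)
#' @param duration_s kernel length (default 32 s)
#' @return numeric kernel sampled at `dt_s`, attribute `dt_s`
#' @export
canonical_hrf <- function(dt_s, peak_s = 6, undershoot_s = 16, ratio = 6,
                          duration_s = 32) {
  stopifnot(dt_s > 0)
  t <- seq(0, duration_s, by = dt_s)
  h <- stats::dgamma(t, shape = peak_s + 1, rate = 1) -
    stats::dgamma(t, shape = undershoot_s + 1, rate = 1) / ratio
  h <- h / max(h)
  attr(h, "dt_s") <- dt_s
  h
}

#' Build the block-design matrix
#'
#' One HRF-convolved boxcar column per task condition plus an intercept,
#' sampled at the signal rate.
#'
#' @param paradigm a `paradigm` (rest rows are ignored as regressors but used
#'   for the overlap check)
#' @param hrf kernel from [canonical_hrf()] (default at `1/fs`)
#' @param fs sampling rate in Hz
#' @return a `design_matrix`: numeric matrix (time x columns) with condition
#'   names plus `"(intercept)"`, attributes `fs` and `conditions`
#' @export
build_design <- function(paradigm, hrf = canonical_hrf(1 / fs), fs = 30) {
  stopifnot(inherits(paradigm, "paradigm") || is.data.frame(paradigm))
  total_s <- attr(paradigm, "total_s")
  if (is.null(total_s)) {
    if (!nrow(paradigm)) stop("empty paradigm needs a total_s attribute")
    total_s <- max(paradigm$onset_s + paradigm$duration_s)
  }
  n <- as.integer(round(total_s * fs))
  ## overlap check across all blocks (task and rest)
  cover <- numeric(n)
  for (i in seq_len(nrow(paradigm))) {
    i0 <- floor(paradigm$onset_s[i] * fs) + 1L
    i1 <- min(n, as.integer(round((paradigm$onset_s[i] +
                                     paradigm$duration_s[i]) * fs)))
    if (i1 >= i0) cover[i0:i1] <- cover[i0:i1] + 1
  }
  if (any(cover > 1 + 1e-9)) stop("overlapping blocks in paradigm")
  conds <- intersect(TASK_CONDITIONS, unique(paradigm$condition))
  cols <- lapply(conds, function(cond) {
    box <- as.numeric(condition_mask(paradigm, cond, fs, n))
    stats::convolve(box, rev(hrf), type = "open")[seq_len(n)]
  })
  X <- cbind(do.call(cbind, c(cols, list(matrix(numeric(0), n, 0)))),
             1)
  colnames(X) <- c(conds, "(intercept)")
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  structure(X, class = c("design_matrix", "matrix"), fs = fs,
            conditions = conds)
}

#' Fit the per-channel GLM
#'
#' Ordinary least squares of each channel on the design, returning the
#' per-condition beta values and residual variance.
#'
#' @param y numeric vector or time x channel matrix (typically the HbDiff
#'   signal)
#' @param design a `design_matrix`
#' @return an `fnirs_glm`: list with `coefficients` (columns = channels),
#'   `sigma2`, `df.residual`, `conditions`
#' @export
fit_glm <- function(y, design) {
  Y <- if (is.null(dim(y))) matrix(y, ncol = 1) else as.matrix(y)
  X <- unclass(design)
  if (nrow(Y) != nrow(X)) {
    stop("signal length (", nrow(Y), ") does not match design (", nrow(X), ")")
  }
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) stop("design matrix is rank deficient")
  beta <- qr.coef(qrx, Y)
  res <- Y - X %*% beta
  structure(list(coefficients = beta,
                 sigma2 = colSums(res^2) / (nrow(X) - ncol(X)),
                 df.residual = nrow(X) - ncol(X),
                 conditions = attr(design, "conditions")),
            class = "fnirs_glm")
}

#' @export
coef.fnirs_glm <- function(object, ...) object$coefficients

#' @export
print.fnirs_glm <- function(x, ...) {
  cat(sprintf("<fnirs_glm> %d regressors x %d channels (df = %d)\n",
              nrow(x$coefficients), ncol(x$coefficients), x$df.residual))
  print(utils::head(t(x$coefficients)))
  invisible(x)
}

#' Group-level contrast across participants
#'
#' One-sample t-test, per channel, of the per-participant contrast value
#' (two-sided, df = n - 1).
#'
#' @param betas participants x channels x conditions array of beta values
#' @param contrast named numeric weight vector over conditions
#' @return data.frame with `channel`, `estimate`, `t`, `df`, `p`, `flagged`
#'   (`TRUE` for degenerate zero-variance channels)
#' @export
group_contrast <- function(betas, contrast) {
  stopifnot(length(dim(betas)) == 3)
  np <- dim(betas)[1]
  if (np < 3) stop("need at least 3 participants")
  conds <- dimnames(betas)[[3]]
  if (is.null(names(contrast)) || !all(names(contrast) %in% conds)) {
    stop("contrast must be named by conditions present in betas")
  }
  w <- stats::setNames(numeric(length(conds)), conds)
  w[names(contrast)] <- contrast
  v <- apply(betas, c(1, 2), function(b) sum(w * b))  # participants x channels
  out <- lapply(seq_len(ncol(v)), function(ch) {
    x <- v[, ch]
    if (stats::sd(x) == 0) {
      return(data.frame(channel = ch, estimate = mean(x), t = NA_real_,
                        df = np - 1, p = NA_real_, flagged = TRUE))
    }
    tt <- stats::t.test(x)
    data.frame(channel = ch, estimate = mean(x), t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value, flagged = FALSE)
  })
  do.call(rbind, out)
}

#' Ratings-as-covariate association with neural contrasts
#'
#' Per channel, regresses the per-participant neural contrast value on the
#' participant's contrast-weighted mean condition rating (nonanswers, rating
#' 0, excluded) and reports the slope and its t-test.
#'
#' @param betas participants x channels x conditions array; the first
#'   dimension must be named with participant ids matching `ratings`
#' @param ratings data.frame with `participant`, `condition`, `rating`
#' @param contrast named weight vector over conditions
#' @return data.frame with `channel`, `slope`, `t`, `df`, `p`, `flagged`
#' @export
covariate_association <- function(betas, ratings, contrast) {
  stopifnot(length(dim(betas)) == 3)
  np <- dim(betas)[1]
  if (np < 3) stop("need at least 3 participants")
  ids <- dimnames(betas)[[1]] %||% as.character(seq_len(np))
  conds <- dimnames(betas)[[3]]
  w <- stats::setNames(numeric(length(conds)), conds)
  w[names(contrast)] <- contrast
  valid <- ratings$rating > 0
  m <- tapply(ratings$rating[valid],
              list(as.character(ratings$participant[valid]),
                   as.character(ratings$condition[valid])), mean)
  cov <- vapply(ids, function(id) {
    mc <- m[id, names(w)[w != 0]]
    sum(w[w != 0] * mc)
  }, numeric(1))
  if (anyNA(cov)) stop("ratings missing for some participants/conditions")
  if (stats::sd(cov) == 0) {
    stop("constant ratings covariate: association undefined")
  }
  v <- apply(betas, c(1, 2), function(b) sum(w * b))
  out <- lapply(seq_len(ncol(v)), function(ch) {
    fit <- stats::lm(v[, ch] ~ cov)
    sm <- summary(fit)$coefficients
    if (nrow(sm) < 2) {
      return(data.frame(channel = ch, slope = NA_real_, t = NA_real_,
                        df = fit$df.residual, p = NA_real_, flagged = TRUE))
    }
    data.frame(channel = ch, slope = sm[2, 1], t = sm[2, 3],
               df = fit$df.residual, p = sm[2, 4], flagged = FALSE)
  })
  do.call(rbind, out)
}
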