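## Orchestration: configuration, input validation diagnostics, and the
## end-to-end synthetic experiment (stimuli -> features -> simulate ->
## preprocess -> GLM -> coherence -> behavior -> report).

#' Default pipeline configuration
#'
#' One root seed deterministically derives the per-stage seeds. The stimulus
#' and dyad counts default to small values so the end-to-end run stays quick;
#' the full study-scale settings are 12 keys and 20 dyads.
#'
#' @param seed root seed
#' @param n_keys number of stimulus keys to compose and analyse (1-12)
#' @param n_dyads number of simulated dyads
#' @param n_raters number of synthetic raters
#' @param sample_rate audio rate for rendering
#' @return a `run_config` list
#' @export
default_config <- function(seed = 1, n_keys = 12, n_dyads = 4, n_raters = 40,
                           sample_rate = 22050) {
  structure(list(seed = seed, n_keys = n_keys, n_dyads = n_dyads,
                 n_raters = n_raters, sample_rate = sample_rate,
                 band = c(10, 20),
                 contrast = c(face_chord = 1, face_nochord = -1),
                 version = as.character(utils::packageVersion("dyadtune"))),
            class = "run_config")
}

#' Run the full synthetic experiment
#'
#' Composes the stimulus set and extracts/compares acoustic features,
#' simulates the requested number of dyads, preprocesses them, fits the GLM
#' and the face_chord - face_nochord group contrast, computes cross-brain
#' coherence with the scrambled-pair null on the coupled channel pairs, and
#' analyses synthetic connectedness ratings. Every stage seed derives from
#' the root seed, so reruns with the same config reproduce the report.
#'
#' @param config a `run_config`, see [default_config()]
#' @param outdir optional directory; when given, CSV summaries and a manifest
#'   are written there
#' @return a `pipeline_report` list: `feature_table`, `feature_comparison`,
#'   `contrast_table`, `coherence_band`, `scrambled_band`, `behavior`,
#'   `condition_means`, `manifest`
#' @export
run_pipeline <- function(config = default_config(), outdir = NULL) {
  stopifnot(inherits(config, "run_config"))
  for (field in c("seed", "n_keys", "n_dyads", "n_raters")) {
    if (is.null(config[[field]])) stop("config is missing field '", field, "'")
  }

  ## stimuli and acoustic features
  sets <- build_stimulus_sets(derive_seed(config$seed, "stimuli"))
  keys <- names(sets$cp)[seq_len(config$n_keys)]
  feat <- lapply(keys, function(k) {
    rbind(extract_features(render_audio(sets$cp[[k]],
                                        sample_rate = config$sample_rate)),
          extract_features(render_audio(sets$ncp[[k]],
                                        sample_rate = config$sample_rate)))
  })
  feature_table <- do.call(rbind, feat)
  is_cp <- grepl("^chord_progression", feature_table$label)
  feature_comparison <- compare_conditions(feature_table[is_cp, ],
                                           feature_table[!is_cp, ])

  ## dyads
  truth <- default_ground_truth()
  fs <- 30
  betas <- NULL
  coh <- list()
  hb_a <- list(); hb_b <- list(); designs <- list(); paradigms <- list()
  pairs <- truth$coupling[, c("channel_a", "channel_b")]
  for (d in seq_len(config$n_dyads)) {
    paradigm <- make_paradigm(order_seed = derive_seed(config$seed,
                                                       paste0("order_", d)))
    dyad <- simulate_dyad(paradigm, truth,
                          rng_seed = derive_seed(config$seed,
                                                 paste0("dyad_", d)),
                          fs = fs, dyad_id = d)
    design <- build_design(paradigm, fs = fs)
    for (p in c("a", "b")) {
      chrom <- preprocess_recording(dyad[[p]])
      fit <- fit_glm(chrom$hbdiff, design)
      b <- t(coef(fit)[TASK_CONDITIONS, , drop = FALSE])  # channel x cond
      betas <- abind_participant(betas, b, paste0("d", d, "_", p))
      if (p == "a") hb_a[[d]] <- chrom$hbdiff else hb_b[[d]] <- chrom$hbdiff
    }
    designs[[d]] <- design
    paradigms[[d]] <- paradigm
    coh[[d]] <- coherence_spectrum(hb_a[[d]], hb_b[[d]], design, paradigm,
                                   pairs, dyad_id = d)
  }
  coh_all <- do.call(rbind, coh)
  contrast_table <- group_contrast(betas, config$contrast)
  ## the paired band test needs >= 3 dyads; smaller smoke runs report NA
  na_band <- list(t = NA_real_, df = NA_real_, p = NA_real_,
                  mean_diff = NA_real_, n_dyads = config$n_dyads,
                  band = config$band)
  coherence_band <- if (config$n_dyads >= 3) {
    band_compare(coh_all, config$band, "face_chord", "face_nochord")
  } else na_band
  scrambled_band <- if (config$n_dyads >= 3) {
    scr <- scrambled_pairs(hb_a, hb_b, designs, paradigms, pairs,
                           rng_seed = derive_seed(config$seed, "scramble"),
                           n_draws = 1)
    band_compare(scr, config$band, "face_chord", "face_nochord")
  } else na_band

  ## behavior
  ratings <- simulate_ratings(config$n_raters,
                              rng_seed = derive_seed(config$seed, "ratings"))
  behavior <- list(kruskal = kruskal_wallis(ratings),
                   games_howell = games_howell(ratings),
                   bonferroni = bonferroni_pairwise_t(ratings))
  cmeans <- condition_means(ratings)

  manifest <- data.frame(
    stage = c("config", "features", "betas", "coherence", "ratings"),
    md5 = c(object_md5(unclass(config)), object_md5(feature_table),
            object_md5(betas), object_md5(coh_all), object_md5(ratings)))

  report <- structure(list(feature_table = feature_table,
                           feature_comparison = feature_comparison,
                           contrast_table = contrast_table,
                           coherence_band = coherence_band,
                           scrambled_band = scrambled_band,
                           behavior = behavior, condition_means = cmeans,
                           manifest = manifest, config = config),
                      class = "pipeline_report")
  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    utils::write.csv(feature_table, file.path(outdir, "features.csv"),
                     row.names = FALSE)
    utils::write.csv(feature_comparison, file.path(outdir, "feature_comparison.csv"),
                     row.names = FALSE)
    utils::write.csv(contrast_table, file.path(outdir, "contrasts.csv"),
                     row.names = FALSE)
    utils::write.csv(coh_all, file.path(outdir, "coherence.csv"),
                     row.names = FALSE)
    utils::write.csv(ratings, file.path(outdir, "ratings.csv"),
                     row.names = FALSE)
    utils::write.csv(manifest, file.path(outdir, "manifest.csv"),
                     row.names = FALSE)
  }
  report
}

## bind one participant's channel x condition beta matrix into the
## participants x channels x conditions array
abind_participant <- function(arr, mat, id) {
  if (is.null(arr)) {
    out <- array(mat, dim = c(1, nrow(mat), ncol(mat)),
                 dimnames = list(id, NULL, colnames(mat)))
    return(out)
  }
  d <- dim(arr)
  out <- array(NA_real_, dim = c(d[1] + 1, d[2], d[3]),
               dimnames = list(c(dimnames(arr)[[1]], id), NULL,
                               dimnames(arr)[[3]]))
  out[seq_len(d[1]), , ] <- arr
  out[d[1] + 1, , ] <- mat
  out
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  stimuli: %d clips, %d features compared\n",
              nrow(x$feature_table), nrow(x$feature_comparison)))
  kb <- x$behavior$kruskal
  cat(sprintf("  ratings omnibus: H(%d) = %.2f, p = %.3g\n", kb$df, kb$H,
              kb$p))
  cb <- x$coherence_band
  cat(sprintf(
    "  coherence band %g-%g s (face_chord - face_nochord): t(%s) = %s, p = %s\n",
    cb$band[1], cb$band[2], format(cb$df), format(round(cb$t, 2)),
    format(signif(cb$p, 3))))
  sig <- sum(x$contrast_table$p < 0.05, na.rm = TRUE)
  cat(sprintf("  contrast channels p < 0.05: %d of %d\n", sig,
              nrow(x$contrast_table)))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Input validation diagnostics

#' Validate a ratings table
#' @param table data.frame to check
#' @return diagnostics data.frame with `check`, `pass`, `message`
#' @export
validate_ratings <- function(table) {
  checks <- list()
  add <- function(check, pass, message = "") {
    checks[[length(checks) + 1L]] <<- data.frame(check = check, pass = pass,
                                                 message = message)
  }
  needed <- c("participant", "condition", "rating")
  missing_cols <- setdiff(needed, names(table))
  add("columns", length(missing_cols) == 0,
      if (length(missing_cols)) paste("missing:", paste(missing_cols,
                                                        collapse = ", "))
      else "")
  if (!length(missing_cols)) {
    bad <- which(table$rating < 0 | table$rating > 5)
    add("rating range 0-5", length(bad) == 0,
        if (length(bad)) paste("out-of-range rating at row(s)",
                               paste(utils::head(bad, 5), collapse = ", "))
        else "")
  }
  do.call(rbind, checks)
}

#' Validate a recording
#' @param rec object expected to be an `fnirs_recording`
#' @return diagnostics data.frame
#' @export
validate_recording <- function(rec) {
  checks <- list()
  add <- function(check, pass, message = "") {
    checks[[length(checks) + 1L]] <<- data.frame(check = check, pass = pass,
                                                 message = message)
  }
  ok_class <- inherits(rec, "fnirs_recording")
  add("class", ok_class, if (!ok_class) "not an fnirs_recording" else "")
  if (ok_class) {
    nw <- dim(rec$od)[3]
    add("three wavelengths", identical(nw, 3L),
        if (!identical(nw, 3L)) paste("found", nw, "wavelengths, need 3")
        else "")
    add("finite values", all(is.finite(rec$od)),
        if (!all(is.finite(rec$od))) "non-finite od values" else "")
    add("sampling rate", isTRUE(rec$sample_rate > 0), "")
  }
  do.call(rbind, checks)
}

#' Validate a paradigm table
#' @param paradigm object expected to be a `paradigm`
#' @return diagnostics data.frame
#' @export
validate_paradigm <- function(paradigm) {
  checks <- list()
  add <- function(check, pass, message = "") {
    checks[[length(checks) + 1L]] <<- data.frame(check = check, pass = pass,
                                                 message = message)
  }
  needed <- c("run", "onset_s", "duration_s", "condition")
  missing_cols <- setdiff(needed, names(paradigm))
  add("columns", length(missing_cols) == 0,
      if (length(missing_cols)) paste("missing:", paste(missing_cols,
                                                        collapse = ", "))
      else "")
  if (!length(missing_cols) && nrow(paradigm)) {
    ord <- order(paradigm$onset_s)
    ends <- paradigm$onset_s[ord] + paradigm$duration_s[ord]
    overlap <- any(utils::head(ends, -1) > paradigm$onset_s[ord][-1] + 1e-9)
    add("non-overlapping blocks", !overlap,
        if (overlap) "blocks overlap in time" else "")
  }
  do.call(rbind, checks)
}
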