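#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded package operations do not
#' disturb the caller's random stream.
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a child seed from a root seed and a label
#'
#' One root seed deterministically drives every stage of the synthetic
#' experiment; children are derived by hashing the label into [0, 2^31).
#' @noRd
derive_seed <- function(root, label) {
  stopifnot(is.numeric(root), length(root) == 1L)
  chars <- utf8ToInt(as.character(label))
  h <- 0
  for (ch in chars) h <- (h * 31 + ch) %% 1000003
  as.integer((abs(root) * 1009 + h) %% (2^31 - 1))
}

## Small numeric helpers -----------------------------------------------------

rms <- function(x) sqrt(mean(x^2))

## md5 of an arbitrary R object (via its serialization), used for manifests.
object_md5 <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  ## version = 2 keeps the hash stable across R >= 3.5
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
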