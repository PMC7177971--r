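#' Derive a reproducible substream seed
#'
#' All randomised stages take an explicit seed. A single run-level seed is
#' turned into per-stage seeds deterministically, so subsetting stages (or
#' pipeline cells) never perturbs another stage's stream.
#'
#' @param seed integer run-level seed.
#' @param stage character label of the stage (and, optionally, an index).
#' @param index optional nonnegative integer, e.g. a resample number.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 48271 + h * 16807 + index * 69621) %% 2147483646)
}

# clamp a numeric vector into [lo, hi]
clamp <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a
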