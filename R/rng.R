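# Per-module random-number substreams. Each substream owns an independent
# Mersenne-Twister state seeded from the master seed and a stream label, so
# adding draws to one module never perturbs another, and paired scenario /
# status quo runs can share cohort- and disease-level draws exactly.

#' Derive a deterministic child seed from a master seed and a stream label
#'
#' A small string hash folded with the master seed; kept strictly below
#' 2^31 so it is always a valid R integer seed.
#'
#' @param seed Master integer seed.
#' @param label Character stream label (e.g. "cohort", "natural_history").
#' @return Integer child seed.
#' @export
substream_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 1009867
  as.integer((abs(as.numeric(seed)) * 2654435 + h * 97 + 12345) %% 2147483629)
}

#' Evaluate an expression under a named random substream
#'
#' Seeds the RNG from [substream_seed()], evaluates `expr`, then restores
#' the caller's RNG state, so module draws are isolated and reproducible.
#'
#' @param seed Master seed.
#' @param label Stream label.
#' @param expr Expression to evaluate.
#' @return Value of `expr`.
#' @export
with_substream <- function(seed, label, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(substream_seed(seed, label))
  expr
}
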