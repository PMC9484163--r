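# Small numeric helpers shared across modules.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Numerically stable softmax
#'
#' @param x Numeric vector of scores.
#' @return Numeric vector of the same length, nonnegative, summing to 1.
#' @keywords internal
softmaxStable <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

#' Derive a stage seed from a global seed
#'
#' A single user-facing seed fans out deterministically to per-stage seeds so
#' that changing one pipeline stage does not perturb the random stream of
#' another. Stage names hash to small offsets; results stay below 2^31.
#'
#' @param seed Integer global seed.
#' @param stage Character stage label.
#' @return Integer seed for the stage.
#' @export
stageSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
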