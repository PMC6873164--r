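#' @keywords internal
"_PACKAGE"

#' @importFrom stats pchisq pt rnorm sd var predict
#' @importFrom utils head tail
NULL

#' Derive a reproducible per-stage seed from a global seed
#'
#' Stage names are hashed to an integer offset so that one global seed
#' deterministically replays every pipeline stage while the stages still
#' draw from distinct streams.
#'
#' @param seed global integer seed.
#' @param stage stage name (a string).
#' @return an integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

# z-score columns over rows, then rescale each column to unit l2-norm.
# Constant columns are zeroed (standardization guard); attribute "zeroed"
# records which ones.
standardize_columns <- function(X) {
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu, "-")
  s <- sqrt(colSums(Xc^2))
  zeroed <- s < 1e-12
  s[zeroed] <- 1
  Xs <- sweep(Xc, 2L, s, "/")
  Xs[, zeroed] <- 0
  attr(Xs, "zeroed") <- which(zeroed)
  Xs
}

`%||%` <- function(a, b) if (is.null(a)) b else a
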