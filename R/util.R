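#' Derive a reproducible child seed from a master seed
#'
#' Deterministically mixes a master seed with one or more integer indices to
#' obtain an independent substream seed.  Used throughout the package so that
#' replicates, initial designs, per-iteration refits and the ensemble coin
#' flips each consume their own stream: dropping or reordering one consumer
#' does not perturb the others.
#'
#' @param seed Master seed (integer-valued).
#' @param ... Integer indices identifying the substream.
#' @return An integer in `[1, 2^31 - 2]`, suitable for [set.seed()].
#' @examples
#' derive_seed(1, 1) != derive_seed(1, 2)
#' @export
derive_seed <- function(seed, ...) {
  idx <- c(...)
  x <- as.double(seed) %% 2147483647
  if (x <= 0) x <- x + 2147483646
  for (k in idx) {
    # Lehmer-style multiplicative step; all intermediates stay below 2^53
    x <- (x * 48271 + (as.double(k) + 1) * 30269) %% 2147483647
    if (x == 0) x <- 1
  }
  as.integer(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert_finite_numeric <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop(sprintf("'%s' must be finite numeric", what), call. = FALSE)
  }
  invisible(x)
}

# rows-of-points coercion: a bare vector is one point, otherwise rows are points
.as_points <- function(x) {
  if (is.null(dim(x))) x <- matrix(as.numeric(x), nrow = 1) else x <- as.matrix(x)
  storage.mode(x) <- "double"
  x
}
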