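#' Matern-family covariance kernel specification
#'
#' The stationary Matern family with smoothness `nu`, length scale `kappa`
#' and variance `sigma2` is the standard choice of Gaussian-process prior for
#' surrogate modelling.  The four half-integer/limit smoothness values
#' `nu = 1/2, 3/2, 5/2, Inf` admit closed forms and are the ones used here:
#'
#' \describe{
#'   \item{Exponential}{`sigma2 * exp(-u / kappa)` (`nu = 1/2`)}
#'   \item{Matern32}{`sigma2 * (1 + s) * exp(-s)`, `s = sqrt(3) u / kappa`}
#'   \item{Matern52}{`sigma2 * (1 + s + s^2/3) * exp(-s)`, `s = sqrt(5) u / kappa`}
#'   \item{RBF}{`sigma2 * exp(-u^2 / (2 kappa^2))` (`nu = Inf`, squared exponential)}
#' }
#'
#' where `u` is the Euclidean distance between the two inputs.  A single
#' isotropic length scale is shared across dimensions; inputs are expected on
#' the normalized unit cube so one scale is meaningful.
#'
#' @param family One of `"Exponential"`, `"Matern32"`, `"Matern52"`, `"RBF"`.
#' @param length_scale Positive length scale `kappa`.
#' @param variance Positive marginal variance `sigma2`.
#' @return An object of class `kernel_spec`.
#' @examples
#' k <- kernel_spec("Matern52", length_scale = 0.3, variance = 2)
#' kernel_value(k, c(0, 0), c(0, 0))  # equals the variance
#' @export
kernel_spec <- function(family = c("Matern52", "RBF", "Matern32", "Exponential"),
                        length_scale = 1, variance = 1) {
  family <- match.arg(family)
  if (!is.numeric(length_scale) || length(length_scale) != 1L ||
      !is.finite(length_scale) || length_scale <= 0) {
    stop("'length_scale' must be a positive finite scalar", call. = FALSE)
  }
  if (!is.numeric(variance) || length(variance) != 1L ||
      !is.finite(variance) || variance <= 0) {
    stop("'variance' must be a positive finite scalar", call. = FALSE)
  }
  structure(list(family = family,
                 length_scale = as.numeric(length_scale),
                 variance = as.numeric(variance)),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf("<kernel_spec> %s kernel: length scale %.6g, variance %.6g\n",
              x$family, x$length_scale, x$variance))
  invisible(x)
}

kernel_families <- function() c("Exponential", "Matern32", "Matern52", "RBF")

# k(u)/sigma2 evaluated elementwise on a distance array U
.kernel_base <- function(family, U, kappa) {
  switch(family,
    Exponential = exp(-U / kappa),
    Matern32 = { s <- sqrt(3) * U / kappa; (1 + s) * exp(-s) },
    Matern52 = { s <- sqrt(5) * U / kappa; (1 + s + s * s / 3) * exp(-s) },
    RBF = exp(-(U * U) / (2 * kappa * kappa)),
    stop("unknown kernel family: ", family, call. = FALSE)
  )
}

# d k / d log(kappa) elementwise on a distance array U
.kernel_dlogkappa <- function(family, U, kappa, sigma2) {
  switch(family,
    Exponential = { r <- U / kappa; sigma2 * r * exp(-r) },
    Matern32 = { s <- sqrt(3) * U / kappa; sigma2 * s * s * exp(-s) },
    Matern52 = { s <- sqrt(5) * U / kappa; sigma2 * (s * s / 3) * (1 + s) * exp(-s) },
    RBF = { r2 <- (U * U) / (kappa * kappa); sigma2 * r2 * exp(-r2 / 2) },
    stop("unknown kernel family: ", family, call. = FALSE)
  )
}

.check_pair <- function(t, t2) {
  .assert_finite_numeric(t, "t")
  .assert_finite_numeric(t2, "t2")
  if (length(t) != length(t2)) {
    stop("points have mismatched dimensions (", length(t), " vs ",
         length(t2), ")", call. = FALSE)
  }
}

#' Evaluate a covariance kernel at a pair of points
#'
#' @param spec A [kernel_spec()].
#' @param t,t2 Numeric vectors of equal length.
#' @return The covariance `k(t, t2)`, a value in `(0, sigma2]`.
#' @examples
#' kernel_value(kernel_spec("Exponential"), 0, 1)  # exp(-1)
#' @export
kernel_value <- function(spec, t, t2) {
  stopifnot(inherits(spec, "kernel_spec"))
  .check_pair(t, t2)
  u <- sqrt(sum((t - t2)^2))
  if (u < 1e-12) return(spec$variance)  # avoid 0*Inf corner in Matern forms
  spec$variance * .kernel_base(spec$family, u, spec$length_scale)
}

# pairwise Euclidean distances between rows of A and rows of B; computed
# dimension-wise so identical points give an exact zero
.cross_dist <- function(A, B) {
  D2 <- matrix(0, nrow(A), nrow(B))
  for (j in seq_len(ncol(A))) {
    D2 <- D2 + outer(A[, j], B[, j], "-")^2
  }
  sqrt(D2)
}

#' Covariance matrix between two point sets
#'
#' Entry `(i, j)` is `kernel_value(spec, A[i, ], B[j, ])`.  With `B = A` the
#' result is a symmetric positive-semidefinite covariance matrix.
#'
#' @param spec A [kernel_spec()].
#' @param A,B Matrices whose rows are points of a common dimension (a bare
#'   vector is taken as a single point).  `B` defaults to `A`.
#' @return An `nrow(A) x nrow(B)` matrix.
#' @export
kernel_matrix <- function(spec, A, B = A) {
  stopifnot(inherits(spec, "kernel_spec"))
  A <- .as_points(A); B <- .as_points(B)
  .assert_finite_numeric(A, "A"); .assert_finite_numeric(B, "B")
  if (ncol(A) != ncol(B)) {
    stop("point sets have mismatched dimensions (", ncol(A), " vs ",
         ncol(B), ")", call. = FALSE)
  }
  U <- .cross_dist(A, B)
  K <- spec$variance * .kernel_base(spec$family, U, spec$length_scale)
  K[U < 1e-12] <- spec$variance
  K
}

#' Kernel gradients with respect to log-hyperparameters
#'
#' Hyperparameters are optimized in log space to keep them positive, so the
#' gradients are reported with respect to `log(kappa)` and `log(sigma2)`.
#' Since the kernel is proportional to `sigma2`, the second component always
#' equals the kernel value itself.
#'
#' @inheritParams kernel_value
#' @return Named numeric vector with components `dlog_length_scale` and
#'   `dlog_variance`.
#' @export
kernel_gradients <- function(spec, t, t2) {
  stopifnot(inherits(spec, "kernel_spec"))
  .check_pair(t, t2)
  u <- sqrt(sum((t - t2)^2))
  k <- kernel_value(spec, t, t2)
  dk <- if (u < 1e-12) 0 else {
    .kernel_dlogkappa(spec$family, u, spec$length_scale, spec$variance)
  }
  c(dlog_length_scale = dk, dlog_variance = k)
}
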