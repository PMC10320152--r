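#' Gaussian-process hyperparameters
#'
#' Bundles a covariance prior with the Gaussian observation-noise variance.
#' Noise is always modelled, even for deterministic objectives, where it
#' absorbs structure the smooth prior cannot capture.
#'
#' @param kernel A [kernel_spec()].
#' @param noise_variance Nonnegative noise variance `sigma_eps^2`.
#' @return An object of class `gp_hyper`.
#' @export
gp_hyperparameters <- function(kernel, noise_variance = 0) {
  stopifnot(inherits(kernel, "kernel_spec"))
  if (!is.numeric(noise_variance) || length(noise_variance) != 1L ||
      !is.finite(noise_variance) || noise_variance < 0) {
    stop("'noise_variance' must be a nonnegative finite scalar", call. = FALSE)
  }
  structure(list(kernel = kernel, noise_variance = as.numeric(noise_variance)),
            class = "gp_hyper")
}

#' @export
print.gp_hyper <- function(x, ...) {
  cat(sprintf("<gp_hyper> %s kernel (kappa %.4g, sigma2 %.4g), noise %.4g\n",
              x$kernel$family, x$kernel$length_scale, x$kernel$variance,
              x$noise_variance))
  invisible(x)
}

#' Center and scale observations
#'
#' Observations are centered by their mean and scaled by their sample
#' standard deviation before Gaussian-process fitting, which makes the
#' zero-mean prior assumption reasonable.  For a single observation or
#' (numerically) constant data the scale falls back to 1.
#'
#' @param y Numeric vector of observations.
#' @return List with the standardized vector `y`, and the `center` and
#'   `scale` of the inverse transform `y_raw = center + scale * y`.
#' @examples
#' standardize_observations(c(1, 3))
#' @export
standardize_observations <- function(y) {
  .assert_finite_numeric(y, "y")
  if (length(y) < 1L) stop("'y' must be non-empty", call. = FALSE)
  center <- mean(y)
  v <- if (length(y) < 2L) 0 else stats::var(y)
  scale <- if (v < 1e-12) 1 else sqrt(v)
  list(y = (y - center) / scale, center = center, scale = scale)
}

# covariance of the observation vector: K + noise*I (jitter added separately)
.obs_cov <- function(X, hyper) {
  K <- kernel_matrix(hyper$kernel, X)
  diag(K) <- diag(K) + hyper$noise_variance
  K
}

# Cholesky with escalating diagonal jitter.  Starts at 1e-8 x mean diagonal,
# escalates tenfold up to 1e-2 x mean diagonal, then gives up.
.chol_jitter <- function(M) {
  n <- nrow(M)
  mdiag <- mean(diag(M))
  jit <- 1e-8 * mdiag
  jit_max <- 1e-2 * mdiag
  while (jit <= jit_max * (1 + 1e-12)) {
    R <- tryCatch(chol(M + diag(jit, n)), error = function(e) NULL)
    if (!is.null(R)) return(list(R = R, jitter = jit))
    jit <- jit * 10
  }
  stop("Cholesky factorization failed even with jitter up to 1e-2 of the ",
       "mean diagonal; the covariance matrix is numerically singular ",
       "(duplicated inputs or degenerate hyperparameters).", call. = FALSE)
}

#' Log marginal likelihood of a Gaussian-process model
#'
#' Computes, via a Cholesky factorization of `K + sigma_eps^2 I` (plus a
#' small recorded jitter),
#' `-1/2 y' (K + sigma_eps^2 I)^-1 y - 1/2 log det(K + sigma_eps^2 I) - n/2 log 2 pi`.
#' The observations are used exactly as given; fitting routines standardize
#' before calling this.
#'
#' @param X Matrix of training inputs (rows are points on the unit cube).
#' @param y Numeric vector of observations, one per row of `X`.
#' @param hyper A [gp_hyperparameters()].
#' @return The log marginal likelihood (scalar).
#' @export
log_marginal_likelihood <- function(X, y, hyper) {
  X <- .as_points(X)
  stopifnot(inherits(hyper, "gp_hyper"), nrow(X) == length(y))
  .assert_finite_numeric(y, "y")
  M <- .obs_cov(X, hyper)
  ch <- .chol_jitter(M)
  a <- backsolve(ch$R, backsolve(ch$R, y, transpose = TRUE))
  n <- length(y)
  -0.5 * sum(y * a) - sum(log(diag(ch$R))) - 0.5 * n * log(2 * pi)
}

# bounds of the log-hyperparameter search box (on normalized inputs and
# standardized observations): log kappa, log sigma2, log noise
.hyper_lower <- log(c(1e-3, 1e-4, 1e-8))
.hyper_upper <- log(c(1e3, 1e4, 1e-1))

# negative LML and its gradient wrt (log kappa, log sigma2, log noise),
# reusing a precomputed distance matrix U
.neg_lml_factory <- function(U, y, family) {
  n <- length(y)
  # L-BFGS-B calls fn and gr at the same point; share the factorization
  cache <- new.env(parent = emptyenv())
  cache$par <- NULL
  compute <- function(par) {
    if (!is.null(cache$par) && identical(cache$par, par)) return(cache$state)
    kappa <- exp(par[1]); sigma2 <- exp(par[2]); noise <- exp(par[3])
    B <- .kernel_base(family, U, kappa)
    M <- sigma2 * B
    diag(M) <- sigma2 + noise
    ch <- tryCatch(.chol_jitter(M), error = function(e) NULL)
    state <- if (is.null(ch)) NULL else {
      a <- backsolve(ch$R, backsolve(ch$R, y, transpose = TRUE))
      list(kappa = kappa, sigma2 = sigma2, noise = noise, B = B,
           R = ch$R, a = a)
    }
    cache$par <- par
    cache$state <- state
    state
  }
  fn <- function(par) {
    st <- compute(par)
    if (is.null(st)) return(1e10)
    0.5 * sum(y * st$a) + sum(log(diag(st$R))) + 0.5 * n * log(2 * pi)
  }
  gr <- function(par) {
    st <- compute(par)
    if (is.null(st)) return(c(0, 0, 0))
    Minv <- chol2inv(st$R)
    # dLML/dtheta = 1/2 tr((aa' - Minv) dM/dtheta); we return the negative
    W <- tcrossprod(st$a) - Minv
    dK_dlk <- .kernel_dlogkappa(family, U, st$kappa, st$sigma2)
    g_lk <- 0.5 * sum(W * dK_dlk)
    g_ls <- 0.5 * sum(W * (st$sigma2 * st$B))  # dM/dlog sigma2 = K
    g_ln <- 0.5 * st$noise * sum(diag(W))
    -c(g_lk, g_ls, g_ln)
  }
  list(fn = fn, gr = gr)
}

#' Fit Gaussian-process hyperparameters by maximum marginal likelihood
#'
#' Maximizes the log marginal likelihood over `log(kappa)`, `log(sigma2)` and
#' `log(noise_variance)` by bounded quasi-Newton ascent (analytic gradients)
#' from multiple log-uniform random starting points, returning the best
#' outcome.  Observations are standardized internally by default, so the
#' returned hyperparameters refer to the standardized scale; [gp_fit()]
#' applies the same convention.
#'
#' @inheritParams log_marginal_likelihood
#' @param family Kernel family name (see [kernel_spec()]).
#' @param n_restarts Number of random restarts (default 10).
#' @param standardize Standardize `y` before fitting (default `TRUE`).
#' @param control List of optimizer settings; `maxit` (default 50) is passed
#'   to [stats::optim()]'s L-BFGS-B method.
#' @return A [gp_hyperparameters()] object.
#' @export
fit_hyperparameters <- function(X, y, family = "Matern52", n_restarts = 10,
                                standardize = TRUE, control = list()) {
  X <- .as_points(X)
  stopifnot(nrow(X) >= 2L, nrow(X) == length(y), n_restarts >= 1L)
  family <- match.arg(family, kernel_families())
  y_fit <- if (standardize) standardize_observations(y)$y else y
  U <- as.matrix(dist(X))
  obj <- .neg_lml_factory(U, y_fit, family)
  maxit <- control$maxit %||% 50
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- .hyper_lower + runif(3) * (.hyper_upper - .hyper_lower)
    res <- tryCatch(
      optim(init, fn = obj$fn, gr = obj$gr, method = "L-BFGS-B",
            lower = .hyper_lower, upper = .hyper_upper,
            control = list(maxit = maxit)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    stop("hyperparameter fitting failed numerically in all restarts",
         call. = FALSE)
  }
  p <- best$par
  gp_hyperparameters(kernel_spec(family, exp(p[1]), exp(p[2])), exp(p[3]))
}

#' Factorize a Gaussian-process model for prediction
#'
#' Computes the Cholesky factor of `K + noise*I + jitter*I` and the solve
#' vector `alpha = (K + noise*I)^-1 y` once (an O(n^3) step), after which
#' posterior means cost O(n) and variances O(n^2) per query.
#'
#' @inheritParams log_marginal_likelihood
#' @param hyper A [gp_hyperparameters()]; if `NULL`, hyperparameters are
#'   fitted first with [fit_hyperparameters()].
#' @param family Kernel family used when `hyper` is `NULL`.
#' @param standardize Standardize observations before fitting/factorizing.
#' @param n_restarts,control Passed to [fit_hyperparameters()] when fitting.
#' @return An object of class `demobo_gp` holding the training data, the
#'   hyperparameters, the standardization, the upper Cholesky factor and
#'   `alpha`, with the applied jitter recorded.
#' @seealso [predict.demobo_gp()]
#' @export
gp_fit <- function(X, y, hyper = NULL, family = "Matern52",
                   standardize = TRUE, n_restarts = 10, control = list()) {
  X <- .as_points(X)
  .assert_finite_numeric(y, "y")
  stopifnot(nrow(X) == length(y), nrow(X) >= 1L)
  if (any(X < -1e-9) || any(X > 1 + 1e-9)) {
    stop("training inputs must lie on the normalized unit cube [0,1]^d",
         call. = FALSE)
  }
  if (is.null(hyper)) {
    hyper <- fit_hyperparameters(X, y, family = family,
                                 n_restarts = n_restarts,
                                 standardize = standardize, control = control)
  }
  stopifnot(inherits(hyper, "gp_hyper"))
  if (standardize) {
    std <- standardize_observations(y)
  } else {
    std <- list(y = y, center = 0, scale = 1)
  }
  M <- .obs_cov(X, hyper)
  ch <- .chol_jitter(M)
  alpha <- backsolve(ch$R, backsolve(ch$R, std$y, transpose = TRUE))
  structure(list(X = X, y_raw = y, y = std$y,
                 center = std$center, scale = std$scale,
                 hyper = hyper, R = ch$R, alpha = as.numeric(alpha),
                 jitter = ch$jitter),
            class = "demobo_gp")
}

#' @export
print.demobo_gp <- function(x, ...) {
  cat(sprintf("<demobo_gp> n = %d, d = %d, %s kernel (kappa %.4g, sigma2 %.4g), noise %.4g\n",
              nrow(x$X), ncol(x$X), x$hyper$kernel$family,
              x$hyper$kernel$length_scale, x$hyper$kernel$variance,
              x$hyper$noise_variance))
  invisible(x)
}

#' Posterior prediction from a fitted Gaussian process
#'
#' Returns the posterior mean and variance of the latent function at each
#' query point, de-standardized back to the observation scale.  The variance
#' is the prior variance minus the information gained from the data, clipped
#' below at zero; observation noise is not added.
#'
#' @param object A `demobo_gp` from [gp_fit()].
#' @param newdata Query point(s): a vector (one point) or a matrix of rows.
#' @param ... Unused.
#' @return List with numeric vectors `mean` and `variance`.
#' @export
predict.demobo_gp <- function(object, newdata, ...) {
  Q <- .as_points(newdata)
  .assert_finite_numeric(Q, "newdata")
  if (ncol(Q) != ncol(object$X)) {
    stop("query dimension (", ncol(Q), ") does not match training dimension (",
         ncol(object$X), ")", call. = FALSE)
  }
  Kq <- kernel_matrix(object$hyper$kernel, Q, object$X)   # m x n
  mean_std <- drop(Kq %*% object$alpha)
  v <- backsolve(object$R, t(Kq), transpose = TRUE)       # n x m
  var_std <- pmax(object$hyper$kernel$variance - colSums(v * v), 0)
  list(mean = object$center + object$scale * mean_std,
       variance = object$scale^2 * var_std)
}
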