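#' Leave-one-out posterior predictions
#'
#' For each training point, the posterior predictive mean and variance at
#' that point of the model fitted (with the *same* hyperparameters, no
#' refitting) on the remaining `n - 1` points.  Computed with the standard
#' rank-one identities from the inverse of the full covariance matrix
#' (`mu_i = y_i - alpha_i / Minv_ii`, `s2_i = 1 / Minv_ii`), which agree with
#' the naive hold-one-out refit; the predictive variance includes the noise
#' variance, i.e. it is the predictive for the held-out observation.
#'
#' Observations are standardized once on the full data (when `standardize`)
#' and predictions are reported on that standardized scale, which is the
#' scale the cross-validation scores are computed on.
#'
#' @inheritParams log_marginal_likelihood
#' @param standardize Standardize `y` (full-data center/scale) first.
#' @return List with vectors `mean`, `variance`, the (standardized)
#'   observations `y`, and the `center`/`scale` used.
#' @export
loo_predictions <- function(X, y, hyper, standardize = TRUE) {
  X <- .as_points(X)
  stopifnot(inherits(hyper, "gp_hyper"), nrow(X) == length(y), length(y) >= 2L)
  std <- if (standardize) standardize_observations(y) else {
    list(y = y, center = 0, scale = 1)
  }
  M <- .obs_cov(X, hyper)
  ch <- .chol_jitter(M)
  Minv <- chol2inv(ch$R)
  a <- drop(Minv %*% std$y)
  dinv <- diag(Minv)
  list(mean = std$y - a / dinv,
       variance = 1 / dinv,
       y = std$y, center = std$center, scale = std$scale)
}

#' Prediction-quality metric for cross-validation
#'
#' Scores a held-out observation against its Gaussian predictive
#' distribution `N(mu, sigma2)`:
#'
#' * `log_density`: `-(y - mu)^2 / (2 sigma2) - log(2 pi sigma2) / 2`, the
#'   log predictive density, which balances accuracy with uncertainty
#'   calibration (it is maximized over `sigma2` at `sigma2 = (y - mu)^2`).
#' * `squared_error`: `-(y - mu)^2 - sigma2`.  Retained for diagnostics
#'   only: it rewards underestimated predictive uncertainty.
#'
#' @param y Held-out observation(s).
#' @param mu,sigma2 Predictive mean(s) and variance(s); `sigma2 > 0` is
#'   required for `log_density`.
#' @param metric `"log_density"` (default) or `"squared_error"`.
#' @return Numeric vector of scores (higher is better).
#' @export
q_metric <- function(y, mu, sigma2, metric = c("log_density", "squared_error")) {
  metric <- match.arg(metric)
  if (metric == "log_density") {
    if (any(sigma2 <= 0)) {
      stop("'sigma2' must be positive for the log_density metric",
           call. = FALSE)
    }
    -(y - mu)^2 / (2 * sigma2) - 0.5 * log(2 * pi * sigma2)
  } else {
    -(y - mu)^2 - sigma2
  }
}

#' Leave-one-out cross-validation score of a kernel family
#'
#' Fits hyperparameters for the family on the (optionally log-transformed,
#' standardized) data, computes leave-one-out predictions with those fixed
#' hyperparameters, and averages the prediction-quality metric.  When the
#' surrogate is destined for the LogEI acquisition the observations must be
#' log-transformed first (`log_transform = TRUE`), so the score is computed
#' on the scale the surrogate will actually model.
#'
#' Hyperparameters are fitted once on the full design and held fixed across
#' the folds; per-fold refits would cost O(n^4) and add little at design
#' sizes of a few dozen points.
#'
#' @inheritParams fit_hyperparameters
#' @param metric Passed to [q_metric()].
#' @param log_transform Apply [transform_for_logei()] to `y` first.
#' @param n_restarts Restarts for the hyperparameter fit.
#' @return An object of class `prior_score`: list with `family`, `score`
#'   (mean of `per_point`), `per_point`, and the `hyper` used.
#' @export
loo_cv_score <- function(X, y, family, metric = "log_density",
                         log_transform = FALSE, n_restarts = 10) {
  X <- .as_points(X)
  stopifnot(nrow(X) == length(y), length(y) >= 2L)
  family <- match.arg(family, kernel_families())
  if (length(y) < 4L) {
    message("LOO-CV on only ", length(y),
            " points: scores are low-information at this design size")
  }
  yy <- if (log_transform) transform_for_logei(y)$values else y
  hyper <- fit_hyperparameters(X, yy, family = family, n_restarts = n_restarts)
  lp <- loo_predictions(X, yy, hyper)
  per <- q_metric(lp$y, lp$mean, lp$variance, metric)
  structure(list(family = family, score = mean(per), per_point = per,
                 hyper = hyper),
            class = "prior_score")
}

#' @export
print.prior_score <- function(x, ...) {
  cat(sprintf("<prior_score> %s: LOO-CV score %.6g over %d points\n",
              x$family, x$score, length(x$per_point)))
  invisible(x)
}

#' Select a covariance prior by leave-one-out cross-validation
#'
#' Scores each candidate kernel family with [loo_cv_score()] on the design
#' and returns the family with the highest score.  Ties are broken by the
#' fixed preference order Matern52, RBF, Matern32, Exponential, reflecting
#' their typical relative fit on log-likelihood surfaces.
#'
#' @inheritParams loo_cv_score
#' @param candidates Character vector of kernel family names.
#' @return The selected family name (character scalar).
#' @export
select_prior <- function(X, y, candidates = kernel_families(),
                         metric = "log_density", log_transform = FALSE,
                         n_restarts = 10) {
  stopifnot(length(candidates) >= 1L)
  candidates <- vapply(candidates, match.arg, "", choices = kernel_families())
  scores <- rep(NA_real_, length(candidates))
  for (i in seq_along(candidates)) {
    s <- tryCatch(
      loo_cv_score(X, y, candidates[i], metric = metric,
                   log_transform = log_transform, n_restarts = n_restarts),
      error = function(e) NULL)
    if (!is.null(s)) scores[i] <- s$score
  }
  if (all(is.na(scores))) {
    stop("LOO-CV scoring failed numerically for every candidate family",
         call. = FALSE)
  }
  pref <- c(Matern52 = 1, RBF = 2, Matern32 = 3, Exponential = 4)
  ok <- which(!is.na(scores))
  ord <- ok[order(-scores[ok], pref[candidates[ok]])]
  unname(candidates[ord[1L]])
}
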