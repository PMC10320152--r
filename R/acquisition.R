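#' Closed-form acquisition values
#'
#' Vectorized closed forms of the three acquisition criteria for a posterior
#' with mean `mu` and standard deviation `sd` at a candidate point, relative
#' to the incumbent (the lowest observed objective value):
#'
#' * `ei_value`: expected improvement
#'   `E[max(0, incumbent - f)] = (incumbent - mu) Phi(z) + sd phi(z)` with
#'   `z = (incumbent - mu)/sd`.
#' * `pi_value`: probability of improvement `Phi(z)`.
#' * `logei_value`: expected improvement when the surrogate models the log
#'   of the (shifted, positive) objective, so `f = exp(g)` with
#'   `g ~ N(mu, sd^2)`:
#'   `E[max(0, c - exp(g))] = c Phi((log c - mu)/sd) - exp(mu + sd^2/2) Phi((log c - mu)/sd - sd)`
#'   where `c` is the shifted incumbent.
#'
#' When `sd` falls below `1e-12` the degenerate limits are returned
#' (`max(0, incumbent - mu)`, the improvement indicator, and
#' `max(0, c - exp(mu))` respectively).
#'
#' @param mu,sd Posterior mean and standard deviation (vectors).
#' @param incumbent Lowest observed objective value (for `logei_value`, the
#'   shifted incumbent `c`, which must be positive).
#' @return Numeric vector of acquisition values; EI and LogEI are
#'   nonnegative, PI lies in `[0, 1]`.
#' @name acquisition-values
NULL

#' @rdname acquisition-values
#' @export
ei_value <- function(mu, sd, incumbent) {
  imp <- incumbent - mu
  out <- ifelse(sd < 1e-12,
                pmax(imp, 0),
                { z <- imp / pmax(sd, 1e-12); imp * pnorm(z) + sd * dnorm(z) })
  pmax(out, 0)
}

#' @rdname acquisition-values
#' @export
pi_value <- function(mu, sd, incumbent) {
  ifelse(sd < 1e-12, as.numeric(mu < incumbent), pnorm((incumbent - mu) / sd))
}

#' @rdname acquisition-values
#' @export
logei_value <- function(mu, sd, incumbent) {
  if (any(incumbent <= 0)) {
    stop("LogEI requires a positive (shifted) incumbent; the log transform ",
         "invariant is violated", call. = FALSE)
  }
  lc <- log(incumbent)
  out <- ifelse(sd < 1e-12,
                pmax(incumbent - exp(mu), 0),
                { z <- (lc - mu) / pmax(sd, 1e-12)
                  incumbent * pnorm(z) - exp(mu + sd^2 / 2) * pnorm(z - sd) })
  pmax(out, 0)
}

#' Acquisition context
#'
#' Couples a fitted surrogate with the incumbent it should improve upon.
#' For LogEI the surrogate must have been trained on `log(y + shift)` (see
#' [transform_for_logei()]); the context then carries the shift so the
#' incumbent can be expressed on the same scale.
#'
#' @param model A `demobo_gp` surrogate.
#' @param y_raw The raw objective values observed so far (original scale);
#'   the incumbent is their minimum.
#' @param log_transformed Was the surrogate trained on log-transformed
#'   observations?
#' @param log_shift Shift applied before the log transform (0 when all
#'   observations were already positive).
#' @return An object of class `acq_context`.
#' @export
acquisition_context <- function(model, y_raw, log_transformed = FALSE,
                                log_shift = 0) {
  stopifnot(inherits(model, "demobo_gp"))
  .assert_finite_numeric(y_raw, "y_raw")
  structure(list(model = model, incumbent = min(y_raw),
                 log_transformed = isTRUE(log_transformed),
                 log_shift = as.numeric(log_shift)),
            class = "acq_context")
}

#' Expected improvement acquisition
#'
#' Emphasizes the size of the expected gain over the incumbent.
#'
#' @param ctx An [acquisition_context()] (not log-transformed).
#' @param t Candidate point(s) on the unit cube (vector or matrix of rows).
#' @return Nonnegative acquisition values, one per candidate.
#' @export
expected_improvement <- function(ctx, t) {
  stopifnot(inherits(ctx, "acq_context"), !ctx$log_transformed)
  p <- predict(ctx$model, t)
  ei_value(p$mean, sqrt(pmax(p$variance, 0)), ctx$incumbent)
}

#' Probability of improvement acquisition
#'
#' Emphasizes the chance of any improvement over the incumbent.
#'
#' @inheritParams expected_improvement
#' @return Values in `[0, 1]`, one per candidate.
#' @export
probability_of_improvement <- function(ctx, t) {
  stopifnot(inherits(ctx, "acq_context"), !ctx$log_transformed)
  p <- predict(ctx$model, t)
  pi_value(p$mean, sqrt(pmax(p$variance, 0)), ctx$incumbent)
}

#' Log expected improvement acquisition
#'
#' Expected improvement for a surrogate trained on the log of the shifted
#' objective, appropriate when modelling positive negative-log-likelihood
#' surfaces whose scale spans orders of magnitude.
#'
#' @param ctx An [acquisition_context()] with `log_transformed = TRUE`.
#' @inheritParams expected_improvement
#' @return Nonnegative acquisition values, bounded above by the shifted
#'   incumbent.
#' @export
log_ei <- function(ctx, t) {
  stopifnot(inherits(ctx, "acq_context"))
  if (!ctx$log_transformed) {
    stop("log_ei requires a log-transformed acquisition context", call. = FALSE)
  }
  p <- predict(ctx$model, t)
  logei_value(p$mean, sqrt(pmax(p$variance, 0)), ctx$incumbent + ctx$log_shift)
}

# dispatch on the acquisition kind
.acq_eval <- function(ctx, kind, t) {
  switch(kind,
         EI = expected_improvement(ctx, t),
         PI = probability_of_improvement(ctx, t),
         LogEI = log_ei(ctx, t),
         stop("unknown acquisition kind: ", kind, call. = FALSE))
}

#' Maximize an acquisition function over the unit cube
#'
#' Draws uniform random candidates, evaluates the acquisition in batch,
#' refines the best few by bounded quasi-Newton ascent, and returns the best
#' point found (ties among equal-valued candidates broken by lowest index).
#' If the proposal lies within `1e-9` (sup norm) of an already evaluated
#' point, the best non-duplicate candidate is returned instead (or a fresh
#' uniform point if every candidate is a duplicate), since duplicated inputs
#' make the covariance matrix singular.
#'
#' @param ctx An [acquisition_context()] matching `kind`.
#' @param kind `"EI"`, `"PI"` or `"LogEI"`.
#' @param space A [search_space()] (supplies the dimension; optimization is
#'   performed on normalized coordinates).
#' @param evaluated Optional matrix of already evaluated unit-cube points for
#'   the duplicate guard.
#' @param n_candidates Number of uniform candidates (default 1000).
#' @param n_refine How many top candidates to refine (default 10).
#' @param refine_maxit L-BFGS-B iteration cap per refinement (default 25).
#' @return A unit-cube point (numeric vector of length `d`).
#' @export
maximize_acquisition <- function(ctx, kind = c("EI", "PI", "LogEI"), space,
                                 evaluated = NULL, n_candidates = 1000,
                                 n_refine = 10, refine_maxit = 25) {
  kind <- match.arg(kind)
  stopifnot(inherits(ctx, "acq_context"))
  d <- if (inherits(space, "search_space")) nrow(space) else as.integer(space)
  cand <- matrix(runif(n_candidates * d), n_candidates, d)
  vals <- .acq_eval(ctx, kind, cand)
  vals[!is.finite(vals)] <- -Inf
  if (all(vals == -Inf)) {
    stop("acquisition evaluated to non-finite values at all candidates",
         call. = FALSE)
  }
  ord <- order(-vals, seq_along(vals))
  best_pt <- cand[ord[1L], ]
  best_val <- vals[ord[1L]]
  neg <- function(p) {
    v <- .acq_eval(ctx, kind, pmin(pmax(p, 0), 1))
    if (!is.finite(v)) 1e10 else -v
  }
  # central-difference gradient evaluated in a single batched prediction
  h <- 1e-6
  neg_gr <- function(p) {
    P <- matrix(rep(p, each = 2L * d), 2L * d, d)
    idx <- rep(seq_len(d), each = 2L)
    P[cbind(seq_len(2L * d), idx)] <- P[cbind(seq_len(2L * d), idx)] +
      rep(c(h, -h), d)
    P <- pmin(pmax(P, 0), 1)
    v <- .acq_eval(ctx, kind, P)
    v[!is.finite(v)] <- 0
    -(v[seq(1, 2 * d, by = 2)] - v[seq(2, 2 * d, by = 2)]) / (2 * h)
  }
  for (i in seq_len(min(n_refine, n_candidates))) {
    start <- cand[ord[i], ]
    res <- tryCatch(
      optim(start, neg, gr = neg_gr, method = "L-BFGS-B", lower = rep(0, d),
            upper = rep(1, d), control = list(maxit = refine_maxit)),
      error = function(e) NULL)
    if (!is.null(res) && is.finite(res$value) && -res$value > best_val) {
      best_val <- -res$value
      best_pt <- pmin(pmax(res$par, 0), 1)
    }
  }
  if (!is.null(evaluated) && nrow(.as_points(evaluated)) > 0) {
    E <- .as_points(evaluated)
    is_dup <- function(p) any(apply(abs(sweep(E, 2, p)), 1, max) < 1e-9)
    if (is_dup(best_pt)) {
      found <- FALSE
      for (i in ord) {
        if (!is_dup(cand[i, ])) { best_pt <- cand[i, ]; found <- TRUE; break }
      }
      if (!found) best_pt <- runif(d)
    }
  }
  as.numeric(best_pt)
}
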