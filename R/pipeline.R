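#' Bounded parameter search space
#'
#' Describes the box of demographic (or other) parameters to optimize over.
#' Each parameter has bounds and a scale: `"linear"` parameters map affinely
#' to `[0, 1]`, `"log"` parameters map via log-interpolation, so that
#' positive scale-spanning quantities (population sizes, split times) are
#' treated log-uniformly by the sampler and the surrogate.
#'
#' @param name Character vector of parameter names.
#' @param lower,upper Numeric bounds, `lower < upper`; `"log"` scale
#'   requires `lower > 0`.
#' @param scale `"linear"` or `"log"`, recycled to the number of parameters.
#' @return A `search_space` (a data frame with one row per parameter).
#' @examples
#' search_space(c("N", "m"), c(1e2, 0), c(1e6, 10), c("log", "linear"))
#' @export
search_space <- function(name, lower, upper, scale = "linear") {
  stopifnot(length(name) == length(lower), length(lower) == length(upper))
  scale <- rep_len(scale, length(name))
  if (!all(scale %in% c("linear", "log"))) {
    stop("'scale' entries must be \"linear\" or \"log\"", call. = FALSE)
  }
  .assert_finite_numeric(lower, "lower"); .assert_finite_numeric(upper, "upper")
  if (any(lower >= upper)) stop("'lower' must be < 'upper'", call. = FALSE)
  if (any(scale == "log" & lower <= 0)) {
    stop("log-scaled parameters require positive lower bounds", call. = FALSE)
  }
  structure(data.frame(name = as.character(name), lower = as.numeric(lower),
                       upper = as.numeric(upper), scale = scale,
                       stringsAsFactors = FALSE),
            class = c("search_space", "data.frame"))
}

#' Map raw parameters to and from the normalized unit cube
#'
#' All surrogate modelling and acquisition maximization happen on
#' `[0, 1]^d`; these maps convert between raw parameter units and normalized
#' coordinates (log-interpolation for log-scaled parameters) and are exact
#' inverses of each other.
#'
#' @param space A [search_space()].
#' @param raw,unit A parameter vector, or a matrix with one point per row.
#' @return The transformed vector/matrix.
#' @export
normalize_point <- function(space, raw) {
  stopifnot(inherits(space, "search_space"))
  P <- .as_points(raw)
  if (ncol(P) != nrow(space)) {
    stop("point dimension does not match the search space", call. = FALSE)
  }
  tol <- 1e-9
  out <- P
  for (j in seq_len(nrow(space))) {
    lo <- space$lower[j]; hi <- space$upper[j]
    if (any(P[, j] < lo - tol * max(1, abs(lo))) ||
        any(P[, j] > hi + tol * max(1, abs(hi)))) {
      stop("parameter '", space$name[j], "' out of bounds", call. = FALSE)
    }
    x <- pmin(pmax(P[, j], lo), hi)
    out[, j] <- if (space$scale[j] == "log") {
      (log(x) - log(lo)) / (log(hi) - log(lo))
    } else {
      (x - lo) / (hi - lo)
    }
  }
  if (is.null(dim(raw))) drop(out) else out
}

#' @rdname normalize_point
#' @export
denormalize_point <- function(space, unit) {
  stopifnot(inherits(space, "search_space"))
  P <- .as_points(unit)
  if (ncol(P) != nrow(space)) {
    stop("point dimension does not match the search space", call. = FALSE)
  }
  if (any(P < -1e-9) || any(P > 1 + 1e-9)) {
    stop("normalized coordinates must lie in [0, 1]", call. = FALSE)
  }
  out <- P
  for (j in seq_len(nrow(space))) {
    lo <- space$lower[j]; hi <- space$upper[j]
    x <- pmin(pmax(P[, j], 0), 1)
    out[, j] <- if (space$scale[j] == "log") {
      exp(log(lo) + x * (log(hi) - log(lo)))
    } else {
      lo + x * (hi - lo)
    }
  }
  if (is.null(dim(unit))) drop(out) else out
}

#' Sample the initial design
#'
#' Draws `size` points i.i.d. uniformly on the normalized unit cube (hence
#' log-uniform in raw units for log-scaled parameters).  The default design
#' size used by the pipelines is `2 d`.
#'
#' @param space A [search_space()].
#' @param size Number of points.
#' @return A `size x d` matrix of unit-cube points.
#' @export
sample_initial_design <- function(space, size) {
  stopifnot(inherits(space, "search_space"), size >= 1L)
  d <- nrow(space)
  matrix(runif(size * d), nrow = size, ncol = d)
}

#' Log-transform observations for the LogEI acquisition
#'
#' LogEI models the logarithm of the objective, which must be positive.
#' Negative log-likelihoods usually are; when they are not, the values are
#' shifted so that the minimum becomes exactly 1 before taking logs, which
#' keeps the transform well-defined and scale-stable.  The shift is carried
#' in the acquisition context and applied to the incumbent consistently.
#'
#' @param y Numeric vector of raw objective values.
#' @return List with `values = log(y + shift)` and the `shift` used
#'   (0 when `min(y) > 0`).
#' @export
transform_for_logei <- function(y) {
  .assert_finite_numeric(y, "y")
  m <- min(y)
  shift <- if (m > 0) 0 else 1 - m
  list(values = log(y + shift), shift = shift)
}

#' Ensemble per-iteration acquisition choice
#'
#' The ensemble pipeline flips a fair coin at each iteration: heads plays
#' probability of improvement, tails log expected improvement.  Consumes one
#' draw from the current RNG stream; [run_bo()] gives the flips a dedicated
#' substream.
#'
#' @return `"PI"` or `"LogEI"`, each with probability 1/2.
#' @export
ensemble_step_choice <- function() {
  if (runif(1) < 0.5) "PI" else "LogEI"
}

#' Pipeline configuration
#'
#' Defines one optimization pipeline: the acquisition mode (a fixed kind, or
#' `"ensemble"` for the per-iteration PI/LogEI coin flip), the prior mode (a
#' fixed kernel family, `"auto"` to select among all four by LOO-CV on the
#' initial design, or `"auto_restricted"` to select between Matern52 and
#' RBF), the evaluation budget, and optimizer settings.
#'
#' @param acquisition `"EI"`, `"PI"`, `"LogEI"` or `"ensemble"`.
#' @param prior A kernel family name, `"auto"`, or `"auto_restricted"`.
#'   Defaults to `"auto_restricted"`, the ensemble pipeline's choice.
#' @param budget Total number of objective evaluations, including the
#'   initial design.  Budgets are best kept under 1000; 200 or 400 are good
#'   practical choices for expensive likelihoods.
#' @param initial_design_size Points in the initial design; defaults to
#'   `2 d` at run time.
#' @param seed Master seed; every random element of a run (design, restarts,
#'   candidates, coin flips) derives from it.
#' @param gp_restarts Hyperparameter-fit restarts per iteration (default 3;
#'   the refit happens at every iteration, so a few restarts suffice).
#' @param gp_maxit L-BFGS-B iteration cap for each hyperparameter fit.
#' @param acq_candidates,acq_refine,acq_refine_maxit Settings of
#'   [maximize_acquisition()].
#' @param loo_metric Metric for automatic prior selection.
#' @return An object of class `bo_config`.
#' @export
bo_config <- function(acquisition = c("ensemble", "EI", "PI", "LogEI"),
                      prior = "auto_restricted", budget = 100,
                      initial_design_size = NULL, seed = 1,
                      gp_restarts = 3, gp_maxit = 40,
                      acq_candidates = 1000, acq_refine = 10,
                      acq_refine_maxit = 25, loo_metric = "log_density") {
  acquisition <- match.arg(acquisition)
  ok_prior <- c(kernel_families(), "auto", "auto_restricted")
  if (!prior %in% ok_prior) {
    stop("'prior' must be a kernel family, \"auto\" or \"auto_restricted\"",
         call. = FALSE)
  }
  stopifnot(budget >= 2, seed == as.integer(seed))
  structure(list(acquisition = acquisition, prior = prior,
                 budget = as.integer(budget),
                 initial_design_size = initial_design_size,
                 seed = as.integer(seed),
                 gp_restarts = as.integer(gp_restarts),
                 gp_maxit = as.integer(gp_maxit),
                 acq_candidates = as.integer(acq_candidates),
                 acq_refine = as.integer(acq_refine),
                 acq_refine_maxit = as.integer(acq_refine_maxit),
                 loo_metric = loo_metric),
            class = "bo_config")
}

#' @export
print.bo_config <- function(x, ...) {
  cat(sprintf("<bo_config> acquisition %s, prior %s, budget %d, seed %d\n",
              x$acquisition, x$prior, x$budget, x$seed))
  invisible(x)
}

# evaluate the objective at a raw point, timing it and catching failures
.evaluate_objective <- function(objective, raw) {
  t0 <- proc.time()[["elapsed"]]
  val <- tryCatch(objective(raw), error = function(e) NA_real_)
  if (!is.numeric(val) || length(val) != 1L || !is.finite(val)) val <- NA_real_
  list(y = val, failed = !is.finite(val),
       wall = proc.time()[["elapsed"]] - t0)
}

#' Run one Bayesian-optimization pipeline
#'
#' Evaluates a random initial design of `2 d` points (uniform on normalized
#' coordinates), selects the covariance prior (fixed, or by LOO-CV on the
#' design for the auto modes), then iterates: choose the acquisition (fixed
#' kind, or the ensemble coin flip), refit the Gaussian-process
#' hyperparameters from scratch on all evaluations so far, maximize the
#' acquisition over the unit cube, evaluate the objective at the proposal,
#' and record the outcome — until the evaluation budget is exhausted.
#'
#' For LogEI iterations the surrogate is trained on the log-transformed
#' (shifted positive) observations; the LOO-CV for a LogEI pipeline's
#' automatic prior uses the same transform, while the ensemble's prior
#' selection uses untransformed observations.  Failed evaluations are
#' flagged and excluded from the surrogate; a run with more than half of
#' its evaluations failed aborts.
#'
#' Every random choice derives deterministically from `config$seed`, so a
#' run is fully reproducible.
#'
#' @param objective Function mapping a raw parameter vector to the value to
#'   minimize (e.g. a negative log-likelihood); see [benchmark_objective()]
#'   and [make_toy_sfs_objective()].
#' @param space A [search_space()].
#' @param config A [bo_config()].
#' @param verbose Print one log line per evaluation (index, phase,
#'   acquisition, raw parameters, value, best-so-far, cumulative wall time).
#' @return An object of class `bo_result`: `history` (a data frame with one
#'   row per evaluation: index, phase, acquisition, raw parameters, `y`,
#'   failure flag, best-so-far, per-evaluation and cumulative wall time),
#'   `incumbent` (list with raw `par` and `value`), the selected `prior`,
#'   the coin-`flips` sequence, and the evaluated unit-cube points.
#' @export
run_bo <- function(objective, space, config, verbose = FALSE) {
  stopifnot(inherits(space, "search_space"), inherits(config, "bo_config"))
  d <- nrow(space)
  n0 <- config$initial_design_size %||% (2L * d)
  n0 <- as.integer(n0)
  budget <- config$budget
  if (budget <= n0) {
    stop("'budget' must exceed the initial design size (", n0, ")",
         call. = FALSE)
  }
  seed <- config$seed

  set.seed(derive_seed(seed, 1))
  unit <- matrix(NA_real_, budget, d)
  unit[seq_len(n0), ] <- sample_initial_design(space, n0)
  raw <- matrix(NA_real_, budget, d, dimnames = list(NULL, space$name))
  y <- rep(NA_real_, budget)
  failed <- rep(FALSE, budget)
  wall <- rep(NA_real_, budget)
  acq_used <- rep(NA_character_, budget)
  phase <- c(rep("initial", n0), rep("bo", budget - n0))

  log_line <- function(i) {
    if (!verbose) return(invisible())
    cat(sprintf("[%3d] %-7s %-5s (%s) y = %-12.6g best = %-12.6g t = %.2fs\n",
                i, phase[i], if (is.na(acq_used[i])) "-" else acq_used[i],
                paste(sprintf("%.6g", raw[i, ]), collapse = ", "),
                y[i], min(y[seq_len(i)], na.rm = TRUE),
                sum(wall[seq_len(i)])))
  }

  for (i in seq_len(n0)) {
    raw[i, ] <- denormalize_point(space, unit[i, ])
    ev <- .evaluate_objective(objective, raw[i, ])
    y[i] <- ev$y; failed[i] <- ev$failed; wall[i] <- ev$wall
    log_line(i)
  }

  n_iter <- budget - n0
  flips <- NULL
  if (config$acquisition == "ensemble") {
    set.seed(derive_seed(seed, 2))
    flips <- vapply(seq_len(n_iter), function(i) ensemble_step_choice(), "")
  }

  # prior: fixed family, or LOO-CV selection on the initial design
  if (config$prior %in% kernel_families()) {
    prior <- config$prior
  } else {
    candidates <- if (config$prior == "auto_restricted") {
      c("Matern52", "RBF")
    } else {
      kernel_families()
    }
    log_tf <- identical(config$acquisition, "LogEI")
    ok <- !failed[seq_len(n0)]
    if (sum(ok) < 2L) {
      stop("too few successful initial evaluations to select a prior",
           call. = FALSE)
    }
    set.seed(derive_seed(seed, 3))
    prior <- select_prior(unit[seq_len(n0), , drop = FALSE][ok, , drop = FALSE],
                          y[seq_len(n0)][ok], candidates = candidates,
                          metric = config$loo_metric, log_transform = log_tf,
                          n_restarts = config$gp_restarts)
  }

  for (it in seq_len(n_iter)) {
    idx <- n0 + it
    kind <- switch(config$acquisition,
                   ensemble = flips[it],
                   config$acquisition)
    done <- seq_len(idx - 1L)
    ok <- done[!failed[done]]
    if (length(ok) < idx - 1L && mean(failed[done]) > 0.5) {
      stop("more than half of the objective evaluations failed; aborting",
           call. = FALSE)
    }
    Xok <- unit[ok, , drop = FALSE]
    yok <- y[ok]
    set.seed(derive_seed(seed, 4, idx))
    gp_ctl <- list(maxit = config$gp_maxit)
    if (kind == "LogEI") {
      tf <- transform_for_logei(yok)
      model <- gp_fit(Xok, tf$values, family = prior,
                      n_restarts = config$gp_restarts, control = gp_ctl)
      ctx <- acquisition_context(model, yok, log_transformed = TRUE,
                                 log_shift = tf$shift)
    } else {
      model <- gp_fit(Xok, yok, family = prior,
                      n_restarts = config$gp_restarts, control = gp_ctl)
      ctx <- acquisition_context(model, yok)
    }
    pt <- maximize_acquisition(ctx, kind, space,
                               evaluated = unit[done, , drop = FALSE],
                               n_candidates = config$acq_candidates,
                               n_refine = config$acq_refine,
                               refine_maxit = config$acq_refine_maxit)
    unit[idx, ] <- pt
    raw[idx, ] <- denormalize_point(space, pt)
    ev <- .evaluate_objective(objective, raw[idx, ])
    y[idx] <- ev$y; failed[idx] <- ev$failed; wall[idx] <- ev$wall
    acq_used[idx] <- kind
    log_line(idx)
  }

  y_eff <- ifelse(failed, Inf, y)
  best <- cummin(y_eff)
  inc_idx <- which.min(y_eff)
  history <- data.frame(index = seq_len(budget), phase = phase,
                        acquisition = acq_used, raw, y = y, failed = failed,
                        best_so_far = best, wall_time = wall,
                        cum_wall_time = cumsum(wall),
                        stringsAsFactors = FALSE)
  structure(list(history = history, unit = unit,
                 incumbent = list(par = raw[inc_idx, ], value = y[inc_idx]),
                 prior = prior, flips = flips, space = space,
                 config = config),
            class = "bo_result")
}

#' @export
print.bo_result <- function(x, ...) {
  cat(sprintf("<bo_result> %s + %s, %d evaluations, best value %.6g\n",
              x$config$acquisition, x$prior, nrow(x$history),
              x$incumbent$value))
  cat("incumbent:", paste(sprintf("%s = %.6g", names(x$incumbent$par),
                                  x$incumbent$par), collapse = ", "), "\n")
  invisible(x)
}

#' Polish an incumbent by bounded quasi-Newton descent
#'
#' Runs L-BFGS-B (numerical gradients) from a starting point, within the box
#' bounds of the space, with a hard cap on objective evaluations.  The
#' returned value never exceeds the starting value: if the descent fails or
#' runs out of evaluations, the best point seen (at worst the start) is
#' returned.
#'
#' @param objective Objective function on raw parameters.
#' @param space A [search_space()].
#' @param start Raw starting point (usually the optimization incumbent).
#' @param max_evals Maximum number of objective evaluations (default 500).
#' @return List with the polished raw `par` and its `value`.
#' @export
local_polish <- function(objective, space, start, max_evals = 500) {
  stopifnot(inherits(space, "search_space"))
  start <- as.numeric(start)
  if (length(start) != nrow(space)) {
    stop("'start' dimension does not match the search space", call. = FALSE)
  }
  normalize_point(space, start)  # bounds check
  env <- new.env()
  env$count <- 0L
  env$best_par <- start
  env$best_val <- Inf
  big <- 1e12
  wrapped <- function(p) {
    if (env$count >= max_evals) stop("demobo_polish_budget", call. = FALSE)
    env$count <- env$count + 1L
    v <- tryCatch(objective(p), error = function(e) NA_real_)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) return(big)
    if (v < env$best_val) { env$best_val <- v; env$best_par <- p }
    v
  }
  f0 <- wrapped(start)
  if (f0 >= big) return(list(par = start, value = f0))
  tryCatch(
    optim(start, wrapped, method = "L-BFGS-B",
          lower = space$lower, upper = space$upper,
          control = list(maxit = 200)),
    error = function(e) NULL)
  list(par = env$best_par, value = env$best_val)
}
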