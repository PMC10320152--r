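#' Construct an objective function with metadata
#'
#' Objectives are plain R functions of a raw parameter vector returning a
#' single finite value to *minimize*, carrying their search space, an
#' optional known optimum, and an optional artificial per-evaluation delay
#' (to emulate expensive likelihood evaluations) as attributes.
#'
#' @param fn Function of a raw parameter vector.
#' @param space The objective's [search_space()].
#' @param known_optimum Optional list with `par` and `value`.
#' @param delay Nonnegative seconds to sleep per evaluation.
#' @return A function of class `bo_objective`.
#' @export
make_objective <- function(fn, space, known_optimum = NULL, delay = 0) {
  stopifnot(is.function(fn), inherits(space, "search_space"), delay >= 0)
  f <- function(par) {
    if (delay > 0) Sys.sleep(delay)
    fn(par)
  }
  structure(f, class = c("bo_objective", "function"), space = space,
            known_optimum = known_optimum, delay = delay)
}

#' @export
print.bo_objective <- function(x, ...) {
  sp <- attr(x, "space")
  cat(sprintf("<bo_objective> %d parameter(s): %s\n", nrow(sp),
              paste(sp$name, collapse = ", ")))
  ko <- attr(x, "known_optimum")
  if (!is.null(ko)) cat(sprintf("known optimum value: %.6g\n", ko$value))
  invisible(x)
}

#' @rdname make_objective
#' @param objective A `bo_objective`.
#' @export
objective_space <- function(objective) attr(objective, "space")

#' @rdname make_objective
#' @export
known_optimum <- function(objective) attr(objective, "known_optimum")

#' Single-population site frequency spectrum
#'
#' An unfolded SFS over `n_chrom` sampled chromosomes: counts of sites at
#' which the derived allele appears `1, ..., n_chrom - 1` times.  The
#' monomorphic corner entries (0 and `n_chrom`) are not part of the data;
#' the on-disk dialect carries them masked.
#'
#' @param counts Nonnegative integer vector of length `n_chrom - 1`.
#' @param n_chrom Number of sampled chromosomes (at least 3).
#' @return An object of class `sfs`.
#' @export
sfs <- function(counts, n_chrom = length(counts) + 1L) {
  if (!is.numeric(counts) || anyNA(counts) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("'counts' must be nonnegative integers", call. = FALSE)
  }
  n_chrom <- as.integer(n_chrom)
  if (n_chrom < 3L) stop("'n_chrom' must be at least 3", call. = FALSE)
  if (length(counts) != n_chrom - 1L) {
    stop("'counts' must have length n_chrom - 1", call. = FALSE)
  }
  structure(list(n_chrom = n_chrom, counts = as.integer(round(counts))),
            class = "sfs")
}

#' @export
print.sfs <- function(x, ...) {
  cat(sprintf("<sfs> unfolded, %d chromosomes, %d segregating sites\n",
              x$n_chrom, sum(x$counts)))
  invisible(x)
}

#' Expected spectrum of the toy SFS model
#'
#' A three-parameter fixture family of expected unfolded spectra,
#' `mu_i = theta * i^(-beta) * exp(-gamma * (i - 1) / (n_chrom - 2))` for
#' `i = 1, ..., n_chrom - 1`.  `theta > 0` sets the overall scale (akin to a
#' mutation-rate-scaled population size), `beta >= 0` the power-law decay
#' towards high frequencies, and `gamma >= 0` an extra exponential
#' high-frequency decay.  This is a test fixture with SFS-like structure,
#' *not* a published demographic model: it gives the optimizer a likelihood
#' surface of the right character without a coalescent or diffusion solver.
#'
#' @param params Numeric vector `c(theta, beta, gamma)`.
#' @param n_chrom Number of sampled chromosomes (at least 3).
#' @return Positive numeric vector of length `n_chrom - 1`.
#' @examples
#' toy_sfs_expected(c(6, 1, 0), 4)  # 6, 3, 2
#' @export
toy_sfs_expected <- function(params, n_chrom) {
  .assert_finite_numeric(params, "params")
  if (length(params) != 3L) {
    stop("'params' must be c(theta, beta, gamma)", call. = FALSE)
  }
  theta <- params[1]; beta <- params[2]; gamma <- params[3]
  if (theta <= 0 || beta < 0 || gamma < 0) {
    stop("toy SFS model requires theta > 0, beta >= 0, gamma >= 0",
         call. = FALSE)
  }
  n_chrom <- as.integer(n_chrom)
  if (n_chrom < 3L) stop("'n_chrom' must be at least 3", call. = FALSE)
  i <- seq_len(n_chrom - 1L)
  theta * i^(-beta) * exp(-gamma * (i - 1) / (n_chrom - 2L))
}

#' Poisson composite negative log-likelihood of a spectrum
#'
#' The standard independent-Poisson composite likelihood of SFS-based
#' inference: `sum_i [mu_i - xi_i log(mu_i) + log(xi_i!)]`, with the
#' factorial term included via `lgamma` so the value is a true negative
#' log-likelihood.
#'
#' @param observed An [sfs()] (or a bare count vector).
#' @param expected Positive expected-count vector of matching length.
#' @return The negative log-likelihood (scalar).
#' @export
sfs_poisson_nll <- function(observed, expected) {
  x <- if (inherits(observed, "sfs")) observed$counts else observed
  if (length(x) != length(expected)) {
    stop("observed and expected spectra have different lengths", call. = FALSE)
  }
  if (any(expected <= 0) || any(!is.finite(expected))) {
    stop("'expected' entries must be positive and finite", call. = FALSE)
  }
  sum(expected - x * log(expected) + lgamma(x + 1))
}

#' Simulate a spectrum from the toy SFS model
#'
#' Draws each entry independently from `Poisson(mu_i)` with the expected
#' spectrum of [toy_sfs_expected()].  Reproducible under [set.seed()].
#'
#' @inheritParams toy_sfs_expected
#' @return An [sfs()].
#' @export
simulate_sfs <- function(params, n_chrom) {
  mu <- toy_sfs_expected(params, n_chrom)
  sfs(rpois(length(mu), mu), n_chrom = n_chrom)
}

#' Default search space of the toy SFS objective
#'
#' `theta` is log-scaled over `[10, 1e5]` (amplitudes span orders of
#' magnitude, as demographic scale parameters do); `beta` and `gamma` are
#' linear over `[0, 3]`.
#'
#' @return A [search_space()].
#' @export
toy_sfs_space <- function() {
  search_space(c("theta", "beta", "gamma"),
               lower = c(10, 0, 0), upper = c(1e5, 3, 3),
               scale = c("log", "linear", "linear"))
}

#' Toy SFS Poisson negative log-likelihood objective
#'
#' Builds the black-box objective `p -> sfs_poisson_nll(observed,
#' toy_sfs_expected(p))` over the toy model's parameter space.  No known
#' optimum is attached (it depends on the data).
#'
#' @param observed An [sfs()].
#' @param space A [search_space()] over `(theta, beta, gamma)`; defaults to
#'   [toy_sfs_space()].
#' @return A [make_objective()] function.
#' @export
make_toy_sfs_objective <- function(observed, space = toy_sfs_space()) {
  stopifnot(inherits(observed, "sfs"))
  n_chrom <- observed$n_chrom
  make_objective(function(par) {
    sfs_poisson_nll(observed, toy_sfs_expected(par, n_chrom))
  }, space = space)
}

#' Standard benchmark objectives
#'
#' Desk-scale stand-ins for expensive log-likelihoods, each with its
#' standard domain and known global minimum attached:
#' `"branin"` (2-d, minimum 0.397887), `"hartmann6"` (6-d, minimum
#' -3.32237), `"rosenbrock"` (2-d, minimum 0 at (1, 1)) and `"sphere"`
#' (2-d, minimum 0 at the origin).
#'
#' @param name Benchmark name.
#' @param delay Optional artificial per-evaluation delay in seconds.
#' @return A [make_objective()] function.
#' @export
benchmark_objective <- function(name = c("branin", "hartmann6", "rosenbrock",
                                         "sphere"), delay = 0) {
  name <- match.arg(name)
  switch(name,
    branin = {
      b <- 5.1 / (4 * pi^2); c2 <- 5 / pi; t0 <- 1 / (8 * pi)
      fn <- function(p) {
        (p[2] - b * p[1]^2 + c2 * p[1] - 6)^2 + 10 * (1 - t0) * cos(p[1]) + 10
      }
      make_objective(fn,
                     search_space(c("x1", "x2"), c(-5, 0), c(10, 15)),
                     known_optimum = list(par = c(-pi, 12.275),
                                          value = 0.397887),
                     delay = delay)
    },
    hartmann6 = {
      A <- matrix(c(10, 3, 17, 3.5, 1.7, 8,
                    0.05, 10, 17, 0.1, 8, 14,
                    3, 3.5, 1.7, 10, 17, 8,
                    17, 8, 0.05, 10, 0.1, 14), 4, 6, byrow = TRUE)
      P <- 1e-4 * matrix(c(1312, 1696, 5569, 124, 8283, 5886,
                           2329, 4135, 8307, 3736, 1004, 9991,
                           2348, 1451, 3522, 2883, 3047, 6650,
                           4047, 8828, 8732, 5743, 1091, 381), 4, 6,
                         byrow = TRUE)
      al <- c(1.0, 1.2, 3.0, 3.2)
      fn <- function(p) {
        Pm <- matrix(p, 4, 6, byrow = TRUE)
        -sum(al * exp(-rowSums(A * (Pm - P)^2)))
      }
      make_objective(fn,
                     search_space(paste0("x", 1:6), rep(0, 6), rep(1, 6)),
                     known_optimum = list(
                       par = c(0.20169, 0.150011, 0.476874,
                               0.275332, 0.311652, 0.6573),
                       value = -3.32237),
                     delay = delay)
    },
    rosenbrock = {
      fn <- function(p) (1 - p[1])^2 + 100 * (p[2] - p[1]^2)^2
      make_objective(fn,
                     search_space(c("x1", "x2"), c(-5, -5), c(10, 10)),
                     known_optimum = list(par = c(1, 1), value = 0),
                     delay = delay)
    },
    sphere = {
      fn <- function(p) sum(p^2)
      make_objective(fn,
                     search_space(c("x1", "x2"), c(-5.12, -5.12),
                                  c(5.12, 5.12)),
                     known_optimum = list(par = c(0, 0), value = 0),
                     delay = delay)
    })
}

#' Read and write single-population spectrum files
#'
#' The plain-text dadi/moments-style dialect for an unfolded
#' single-population spectrum:
#' line 1 is `"<n_chrom + 1> unfolded"`; line 2 holds the `n_chrom + 1`
#' spectrum entries for derived-allele counts `0, ..., n_chrom` (the two
#' monomorphic corners are present but ignored); line 3 is a 0/1 mask with
#' ones at both corners.  `read_sfs(write_sfs(s, path))` restores `s`
#' exactly.  Folded spectra are not supported.
#'
#' @param path File path.
#' @return `read_sfs` returns an [sfs()]; `write_sfs` returns `path`
#'   invisibly.
#' @export
read_sfs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L) {
    stop("malformed spectrum file (expected 3 lines, got ", length(lines),
         ")", call. = FALSE)
  }
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hdr) < 2L || is.na(suppressWarnings(as.integer(hdr[1])))) {
    stop("line 1: malformed header '", lines[1], "'", call. = FALSE)
  }
  if (hdr[2] != "unfolded") {
    stop("line 1: only unfolded spectra are supported (got '", hdr[2], "')",
         call. = FALSE)
  }
  len <- as.integer(hdr[1])
  vals <- suppressWarnings(as.numeric(strsplit(trimws(lines[2]), "\\s+")[[1]]))
  if (length(vals) != len || anyNA(vals)) {
    stop("line 2: expected ", len, " numeric entries", call. = FALSE)
  }
  if (any(vals < 0)) stop("line 2: negative counts", call. = FALSE)
  mask <- suppressWarnings(as.integer(strsplit(trimws(lines[3]), "\\s+")[[1]]))
  if (length(mask) != len || anyNA(mask) || !all(mask %in% c(0L, 1L))) {
    stop("line 3: expected ", len, " 0/1 mask entries", call. = FALSE)
  }
  if (mask[1] != 1L || mask[len] != 1L) {
    stop("line 3: corner entries must be masked (1)", call. = FALSE)
  }
  sfs(vals[-c(1L, len)], n_chrom = len - 1L)
}

#' @rdname read_sfs
#' @param x An [sfs()] to write.
#' @export
write_sfs <- function(x, path) {
  stopifnot(inherits(x, "sfs"))
  len <- x$n_chrom + 1L
  lines <- c(paste(len, "unfolded"),
             paste(c(0L, x$counts, 0L), collapse = " "),
             paste(c(1L, rep(0L, x$n_chrom - 1L), 1L), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}
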