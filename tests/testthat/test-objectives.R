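test_that("the toy expected spectrum follows its closed form", {
  expect_equal(toy_sfs_expected(c(6, 1, 0), 4), c(6, 3, 2))
  expect_equal(toy_sfs_expected(c(7, 0, 0), 6), rep(7, 5))
  expect_equal(toy_sfs_expected(c(1, 0, 1), 4),
               c(1, exp(-0.5), exp(-1)))
  expect_error(toy_sfs_expected(c(-1, 0, 0), 5), "theta")
  expect_error(toy_sfs_expected(c(1, 1), 5), "params")
})

test_that("the Poisson composite NLL matches hand arithmetic", {
  expect_equal(sfs_poisson_nll(1, 1), 1)
  expect_equal(sfs_poisson_nll(0, 2), 2)
  expect_equal(sfs_poisson_nll(2, 2), 2 - 2 * log(2) + log(2),
               tolerance = 1e-12)
  expect_error(sfs_poisson_nll(c(1, 2), c(1, 0)), "positive")
  expect_error(sfs_poisson_nll(c(1, 2), 1), "length")
  # minimized over the expectation at the observed counts (Poisson MLE)
  x <- c(5, 3, 1)
  nll_at <- function(f) sfs_poisson_nll(x, x * f)
  fac <- seq(0.5, 2, length.out = 61)
  expect_equal(fac[which.min(vapply(fac, nll_at, 0))], 1, tolerance = 0.02)
})

test_that("simulated spectra have Poisson moments and fixed-seed identity", {
  params <- c(50, 0.5, 0.3)
  mu <- toy_sfs_expected(params, 6)
  set.seed(61)
  R <- 2000
  draws <- matrix(0, R, 5)
  for (r in seq_len(R)) draws[r, ] <- simulate_sfs(params, 6)$counts
  expect_true(all(abs(colMeans(draws) - mu) < 3 * sqrt(mu / R) + 0.05))
  set.seed(8); s1 <- simulate_sfs(params, 6)
  set.seed(8); s2 <- simulate_sfs(params, 6)
  expect_identical(s1, s2)
})

test_that("the toy objective is a deterministic bounded-below NLL", {
  set.seed(62)
  truth <- c(1000, 1, 0.5)
  obs <- simulate_sfs(truth, 20)
  obj <- make_toy_sfs_objective(obs)
  v1 <- obj(truth); v2 <- obj(truth)
  expect_identical(v1, v2)
  # the saturated model (expectation = observed counts) bounds the NLL below
  saturated <- sfs_poisson_nll(obs, pmax(obs$counts, 1e-9))
  expect_gte(v1, saturated)
  # the theta slice through the truth is unimodal on a grid
  th <- exp(seq(log(500), log(2000), length.out = 100))
  nll <- vapply(th, function(t) obj(c(t, 1, 0.5)), 0)
  drops <- diff(nll) < 0
  expect_equal(sum(diff(drops) != 0), 1L)  # decreasing then increasing
})

test_that("benchmark objectives evaluate to their known optima", {
  sph <- benchmark_objective("sphere")
  expect_equal(sph(c(0, 0)), 0)
  ros <- benchmark_objective("rosenbrock")
  expect_equal(ros(c(1, 1)), 0)
  bra <- benchmark_objective("branin")
  ko <- known_optimum(bra)
  expect_equal(bra(ko$par), ko$value, tolerance = 1e-6)
  har <- benchmark_objective("hartmann6")
  ko6 <- known_optimum(har)
  expect_equal(har(ko6$par), ko6$value, tolerance = 1e-4)
  expect_error(benchmark_objective("ackley"))
})

test_that("benchmark objectives are finite across their domains", {
  set.seed(63)
  for (name in c("branin", "hartmann6", "rosenbrock", "sphere")) {
    obj <- benchmark_objective(name)
    sp <- objective_space(obj)
    P <- denormalize_point(sp, matrix(runif(1000 * nrow(sp)), ncol = nrow(sp)))
    vals <- apply(P, 1, obj)
    expect_true(all(is.finite(vals)))
  }
})

test_that("spectrum files round-trip through the dadi-style dialect", {
  set.seed(64)
  s <- simulate_sfs(c(200, 1, 0.2), 12)
  path <- withr::local_tempfile(fileext = ".fs")
  write_sfs(s, path)
  expect_identical(read_sfs(path), s)
  lines <- readLines(path)
  expect_identical(lines[1], "13 unfolded")
  expect_length(strsplit(lines[2], " ")[[1]], 13L)
})

test_that("malformed spectrum files are rejected with line context", {
  path <- withr::local_tempfile(fileext = ".fs")
  writeLines(c("5 unfolded", "0 6 3 2 0", "1 0 0 0 1"), path)
  s <- read_sfs(path)
  expect_equal(s$n_chrom, 4L)
  expect_equal(s$counts, c(6L, 3L, 2L))
  writeLines(c("5 folded", "0 6 3 2 0", "1 0 0 0 1"), path)
  expect_error(read_sfs(path), "unfolded")
  writeLines(c("5 unfolded", "0 6 3 0", "1 0 0 0 1"), path)
  expect_error(read_sfs(path), "line 2")
  writeLines(c("5 unfolded", "0 6 -3 2 0", "1 0 0 0 1"), path)
  expect_error(read_sfs(path), "negative")
  writeLines(c("5 unfolded", "0 6 3 2 0", "0 0 0 0 1"), path)
  expect_error(read_sfs(path), "corner")
})

test_that("spectrum construction enforces its invariants", {
  expect_error(sfs(c(1, -2, 3)), "nonnegative")
  expect_error(sfs(c(1, 2), n_chrom = 5), "length")
  expect_error(sfs(1, n_chrom = 2), "at least 3")
})

test_that("an artificial delay slows evaluation as configured", {
  obj <- benchmark_objective("sphere", delay = 0.05)
  t0 <- proc.time()[["elapsed"]]
  obj(c(1, 1))
  expect_gte(proc.time()[["elapsed"]] - t0, 0.04)
})
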