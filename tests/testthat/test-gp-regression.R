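test_that("standardization follows the centered, sample-SD convention", {
  s <- standardize_observations(c(1, 3))
  expect_equal(s$center, 2)
  expect_equal(s$scale, sqrt(2))
  expect_equal(s$y, c(-1, 1) / sqrt(2))
  # single point and constant data fall back to scale 1
  expect_equal(standardize_observations(5), list(y = 0, center = 5, scale = 1))
  expect_equal(standardize_observations(c(2, 2, 2)),
               list(y = c(0, 0, 0), center = 2, scale = 1))
  set.seed(1)
  y <- rnorm(20, 3, 7)
  s <- standardize_observations(y)
  expect_equal(mean(s$y), 0, tolerance = 1e-12)
  expect_equal(sd(s$y), 1, tolerance = 1e-12)
  expect_equal(s$center + s$scale * s$y, y, tolerance = 1e-12)
})

test_that("log marginal likelihood matches the scalar closed form", {
  X <- matrix(0.5, 1, 1)
  h <- gp_hyperparameters(kernel_spec("RBF", 1, 0.4), 0.6)
  expect_equal(log_marginal_likelihood(X, 0, h), -0.5 * log(2 * pi),
               tolerance = 1e-6)
  y1 <- 1.7
  h2 <- gp_hyperparameters(kernel_spec("Matern32", 1, 2), 0.5)
  expect_equal(log_marginal_likelihood(X, y1, h2),
               -y1^2 / (2 * 2.5) - 0.5 * log(2.5) - 0.5 * log(2 * pi),
               tolerance = 1e-6)
})

test_that("log marginal likelihood agrees with the dense-density oracle", {
  set.seed(7)
  for (rep in 1:10) {
    tr <- random_training(6, 2)
    h <- random_hyper()
    expect_equal(log_marginal_likelihood(tr$X, tr$y, h),
                 dense_lml_oracle(tr$X, tr$y, h), tolerance = 1e-8)
  }
})

test_that("factorization reconstructs the covariance and solves exactly", {
  set.seed(8)
  tr <- random_training(9, 3)
  h <- random_hyper("Matern52")
  fit <- gp_fit(tr$X, tr$y, hyper = h, standardize = FALSE)
  M <- kernel_matrix(h$kernel, tr$X)
  diag(M) <- diag(M) + h$noise_variance + fit$jitter
  expect_equal(crossprod(fit$R), M, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(drop(M %*% fit$alpha), tr$y, tolerance = 1e-8)
  # scalar case: alpha = y / sigma2 when noiseless
  f1 <- gp_fit(matrix(0.3, 1, 1), 2.4,
               hyper = gp_hyperparameters(kernel_spec("RBF", 1, 3), 0),
               standardize = FALSE)
  expect_equal(f1$alpha, 2.4 / 3, tolerance = 1e-6)
})

test_that("posterior predictions match dense Gaussian conditioning", {
  set.seed(9)
  for (standardize in c(TRUE, FALSE)) {
    tr <- random_training(8, 2)
    h <- random_hyper()
    fit <- gp_fit(tr$X, tr$y, hyper = h, standardize = standardize)
    Q <- matrix(runif(10), 5, 2)
    p <- predict(fit, Q)
    o <- dense_posterior_oracle(tr$X, tr$y, h, Q, standardize = standardize)
    expect_equal(p$mean, o$mean, tolerance = 1e-8)
    expect_equal(p$variance, o$variance, tolerance = 1e-8)
  }
})

test_that("a noiseless GP interpolates its training data", {
  set.seed(10)
  tr <- random_training(6, 2)
  h <- gp_hyperparameters(kernel_spec("RBF", 0.5, 1.5), 0)
  fit <- gp_fit(tr$X, tr$y, hyper = h)
  p <- predict(fit, tr$X)
  expect_equal(p$mean, tr$y, tolerance = 1e-6)
  expect_true(all(p$variance < 1e-6))
})

test_that("single-point posterior matches the analytic closed form", {
  # one noiseless observation y = 1 at t = 0, RBF(kappa 1, sigma2 1):
  # mean(t) = exp(-t^2/2), var(t) = 1 - exp(-t^2)
  fit <- gp_fit(matrix(0, 1, 1), 1,
                hyper = gp_hyperparameters(kernel_spec("RBF", 1, 1), 0),
                standardize = FALSE)
  t <- c(0.2, 0.5, 0.9)
  p <- predict(fit, matrix(t, 3, 1))
  expect_equal(p$mean, exp(-t^2 / 2), tolerance = 1e-6)
  expect_equal(p$variance, 1 - exp(-t^2), tolerance = 1e-6)
})

test_that("posterior variance is bounded by the prior and shrinks with data", {
  set.seed(11)
  h <- random_hyper("Matern32")
  tr <- random_training(10, 2)
  Q <- matrix(runif(12), 6, 2)
  fit_all <- gp_fit(tr$X, tr$y, hyper = h, standardize = FALSE)
  p_all <- predict(fit_all, Q)
  expect_true(all(p_all$variance <= h$kernel$variance + 1e-8))
  # dropping a training point can only increase posterior variance
  fit_less <- gp_fit(tr$X[-1, ], tr$y[-1], hyper = h, standardize = FALSE)
  p_less <- predict(fit_less, Q)
  expect_true(all(p_all$variance <= p_less$variance + 1e-8))
})

test_that("predictions and likelihood are invariant to training order", {
  set.seed(12)
  tr <- random_training(9, 2)
  h <- random_hyper()
  perm <- sample(9)
  q <- runif(2)
  f1 <- gp_fit(tr$X, tr$y, hyper = h)
  f2 <- gp_fit(tr$X[perm, ], tr$y[perm], hyper = h)
  expect_equal(predict(f1, q)$mean, predict(f2, q)$mean, tolerance = 1e-8)
  expect_equal(predict(f1, q)$variance, predict(f2, q)$variance,
               tolerance = 1e-8)
  expect_equal(log_marginal_likelihood(tr$X, tr$y, h),
               log_marginal_likelihood(tr$X[perm, ], tr$y[perm], h),
               tolerance = 1e-8)
})

test_that("restarted fitting never does worse than a single restart", {
  set.seed(13)
  X <- matrix(runif(40), 40, 1)
  y <- sin(5 * X[, 1]) + rnorm(40, 0, 0.1)
  ys <- standardize_observations(y)$y
  set.seed(99)
  h1 <- fit_hyperparameters(X, y, "RBF", n_restarts = 1)
  set.seed(99)
  h10 <- fit_hyperparameters(X, y, "RBF", n_restarts = 10)
  expect_gte(log_marginal_likelihood(X, ys, h10) + 1e-9,
             log_marginal_likelihood(X, ys, h1))
})

test_that("fitting recovers a known RBF length scale", {
  # data simulated from RBF(kappa 0.2, sigma2 1) + noise 1e-4, n = 60, d = 1
  set.seed(14)
  spec <- kernel_spec("RBF", 0.2, 1)
  hits <- 0L
  for (rep in 1:20) {
    X <- matrix(runif(60), 60, 1)
    y <- sample_gp(X, spec, noise_variance = 1e-4)
    h <- fit_hyperparameters(X, y, "RBF", n_restarts = 10,
                             standardize = FALSE)
    k <- h$kernel$length_scale
    if (k > 0.1 && k < 0.4) hits <- hits + 1L
  }
  expect_gte(hits, 16L)  # within a factor of 2 of truth in >= 80% of runs
})

test_that("fitted variance scales quadratically with the observations", {
  set.seed(15)
  spec <- kernel_spec("RBF", 0.3, 1)
  X <- matrix(runif(50), 50, 1)
  y <- sample_gp(X, spec, noise_variance = 1e-4)
  set.seed(77)
  h1 <- fit_hyperparameters(X, y, "RBF", standardize = FALSE)
  set.seed(77)
  h2 <- fit_hyperparameters(X, 2 * y, "RBF", standardize = FALSE)
  ratio <- h2$kernel$variance / h1$kernel$variance
  expect_equal(ratio, 4, tolerance = 0.2 * 4)
})

test_that("degenerate and invalid GP inputs raise errors", {
  expect_error(gp_fit(matrix(2, 1, 1), 1,
                      hyper = gp_hyperparameters(kernel_spec("RBF"), 0)),
               "unit cube")
  fit <- gp_fit(matrix(0.5, 1, 1), 1,
                hyper = gp_hyperparameters(kernel_spec("RBF"), 0))
  expect_error(predict(fit, c(0.1, 0.2)), "dimension")
  expect_error(gp_hyperparameters(kernel_spec("RBF"), -1), "nonnegative")
  # duplicated points are rescued by the jitter ladder, which is recorded
  Xdup <- matrix(0.5, 6, 1)
  h0 <- gp_hyperparameters(kernel_spec("RBF", 1, 1), 0)
  fdup <- gp_fit(Xdup, rep(1, 6), hyper = h0, standardize = FALSE)
  expect_gt(fdup$jitter, 0)
  # an indefinite matrix defeats every jitter level and raises the error
  expect_error(demobo:::.chol_jitter(matrix(c(1, 2, 2, 1), 2, 2)), "jitter")
})
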