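# Monte-Carlo estimates of the defining improvement expectations, used as
# independent oracles for the closed forms.
mc_ei <- function(mu, sd, inc, n = 2e5) {
  f <- rnorm(n, mu, sd)
  est <- mean(pmax(inc - f, 0))
  list(est = est, se = sd(pmax(inc - f, 0)) / sqrt(n))
}
mc_pi <- function(mu, sd, inc, n = 2e5) {
  p <- mean(rnorm(n, mu, sd) < inc)
  list(est = p, se = sqrt(p * (1 - p) / n) + 1e-12)
}
mc_logei <- function(mu, sd, cshift, n = 2e5) {
  g <- rnorm(n, mu, sd)
  imp <- pmax(cshift - exp(g), 0)
  list(est = mean(imp), se = sd(imp) / sqrt(n))
}

test_that("expected improvement matches its closed form and expectation", {
  expect_equal(ei_value(0, 1, 0), dnorm(0), tolerance = 1e-12)
  expect_equal(ei_value(1, 1e-15, 0), 0)        # no improvement possible
  expect_equal(ei_value(-0.5, 1e-15, 0), 0.5)   # certain improvement
  set.seed(21)
  for (rep in 1:10) {
    mu <- rnorm(1); sd <- runif(1, 0.2, 2); inc <- mu + runif(1, -2, 2) * sd
    mc <- mc_ei(mu, sd, inc)
    expect_lt(abs(ei_value(mu, sd, inc) - mc$est), 3 * mc$se + 1e-12)
  }
})

test_that("probability of improvement matches its closed form and frequency", {
  expect_equal(pi_value(0, 1, 0), 0.5)
  expect_equal(pi_value(1, 1, 0), pnorm(-1), tolerance = 1e-12)
  expect_gte(pi_value(10, 1, 20), 1 - 1e-15)  # 10-sigma certain improvement
  set.seed(22)
  for (rep in 1:10) {
    mu <- rnorm(1); sd <- runif(1, 0.2, 2); inc <- mu + runif(1, -2, 2) * sd
    mc <- mc_pi(mu, sd, inc)
    expect_lt(abs(pi_value(mu, sd, inc) - mc$est), 3 * mc$se + 1e-12)
  }
})

test_that("log expected improvement matches its lognormal closed form", {
  # c = 1, mu = 0, sd = 1: Phi(0) - exp(1/2) Phi(-1)
  expect_equal(logei_value(0, 1, 1), pnorm(0) - exp(0.5) * pnorm(-1),
               tolerance = 1e-12)
  expect_equal(logei_value(1, 1e-15, 1), 0)  # exp(mu) >= c, no mass
  set.seed(23)
  for (rep in 1:10) {
    mu <- runif(1, -1, 2); sd <- runif(1, 0.2, 1)
    cshift <- exp(mu + runif(1, -1, 1))
    mc <- mc_logei(mu, sd, cshift)
    expect_lt(abs(logei_value(mu, sd, cshift) - mc$est), 3 * mc$se + 1e-12)
    # improvement is bounded by the shifted incumbent
    expect_lte(logei_value(mu, sd, cshift), cshift)
  }
  expect_error(logei_value(0, 1, -2), "positive")
})

test_that("acquisitions respond monotonically to the posterior", {
  mus <- seq(-2, 2, length.out = 41)
  ei <- ei_value(mus, 1, 0)
  pi <- pi_value(mus, 1, 0)
  expect_true(all(diff(ei) < 0))
  expect_true(all(diff(pi) < 0))
  sds <- seq(0.1, 3, length.out = 30)
  expect_true(all(diff(ei_value(0.5, sds, 0)) > 0))  # mu above incumbent
  expect_true(all(ei_value(rnorm(20), runif(20, 0, 2), 0) >= 0))
  p <- pi_value(rnorm(20), runif(20, 0, 2), 0)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("context wrappers tie acquisitions to the surrogate", {
  set.seed(24)
  tr <- random_training(8, 1)
  h <- random_hyper("Matern52")
  fit <- gp_fit(tr$X, tr$y, hyper = h)
  ctx <- acquisition_context(fit, tr$y)
  expect_equal(ctx$incumbent, min(tr$y))
  q <- matrix(runif(4), 4, 1)
  p <- predict(fit, q)
  expect_equal(expected_improvement(ctx, q),
               ei_value(p$mean, sqrt(p$variance), min(tr$y)),
               tolerance = 1e-12)
  expect_error(log_ei(ctx, q), "log-transformed")
  # log context: surrogate fitted on log(y + shift)
  tf <- transform_for_logei(tr$y)
  fitl <- gp_fit(tr$X, tf$values, hyper = h)
  ctxl <- acquisition_context(fitl, tr$y, log_transformed = TRUE,
                              log_shift = tf$shift)
  expect_error(expected_improvement(ctxl, q))
  expect_true(all(log_ei(ctxl, q) >= 0))
})

test_that("acquisition maximization beats a dense 1-d grid", {
  set.seed(25)
  X <- matrix(c(0.1, 0.35, 0.6, 0.85), 4, 1)
  y <- c(0.8, -0.4, 0.3, -0.1)
  fit <- gp_fit(X, y, hyper = gp_hyperparameters(
    kernel_spec("Matern52", 0.2, 1), 1e-6))
  ctx <- acquisition_context(fit, y)
  sp <- search_space("x", 0, 1)
  for (kind in c("EI", "PI")) {
    pt <- maximize_acquisition(ctx, kind, sp)
    grid <- matrix(seq(0, 1, length.out = 1e4), ncol = 1)
    best_grid <- max(demobo:::.acq_eval(ctx, kind, grid))
    expect_gte(demobo:::.acq_eval(ctx, kind, matrix(pt, 1, 1)),
               best_grid - 1e-6)
  }
})

test_that("acquisition maximization is reproducible and guards duplicates", {
  set.seed(26)
  tr <- random_training(6, 2)
  fit <- gp_fit(tr$X, tr$y, hyper = random_hyper())
  ctx <- acquisition_context(fit, tr$y)
  sp <- search_space(c("a", "b"), c(0, 0), c(1, 1))
  set.seed(5); p1 <- maximize_acquisition(ctx, "EI", sp)
  set.seed(5); p2 <- maximize_acquisition(ctx, "EI", sp)
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0 & p1 <= 1))
  # proposing an already evaluated point falls back to a fresh one
  set.seed(5)
  p3 <- maximize_acquisition(ctx, "EI", sp, evaluated = matrix(p1, 1, 2))
  expect_gt(max(abs(p3 - p1)), 1e-9)
})

test_that("a flat surrogate still yields a feasible proposal", {
  # constant observations: posterior is flat, acquisition near-constant
  X <- matrix(c(0.2, 0.8), 2, 1)
  fit <- gp_fit(X, c(1, 1), hyper = gp_hyperparameters(
    kernel_spec("RBF", 1, 1), 1e-6))
  ctx <- acquisition_context(fit, c(1, 1))
  pt <- maximize_acquisition(ctx, "PI", search_space("x", 0, 1))
  expect_true(is.finite(pt) && pt >= 0 && pt <= 1)
})
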