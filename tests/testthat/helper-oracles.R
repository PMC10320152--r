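# Independent dense-linear-algebra oracles and simulation fixtures.
# These deliberately avoid the package's Cholesky/rank-one code paths:
# everything goes through solve() on explicitly formed matrices.

# starting jitter used by the package's factorizations (documented constant)
base_jitter <- function(M) 1e-8 * mean(diag(M))

obs_cov_oracle <- function(X, hyper, jitter = NULL) {
  M <- kernel_matrix(hyper$kernel, X)
  diag(M) <- diag(M) + hyper$noise_variance
  if (is.null(jitter)) jitter <- base_jitter(M)
  diag(M) <- diag(M) + jitter
  M
}

# log density of N(0, K + noise I + jitter I) at y, by dense determinant/solve
dense_lml_oracle <- function(X, y, hyper) {
  M <- obs_cov_oracle(X, hyper)
  n <- length(y)
  ld <- as.numeric(determinant(M, logarithm = TRUE)$modulus)
  -0.5 * drop(t(y) %*% solve(M, y)) - 0.5 * ld - 0.5 * n * log(2 * pi)
}

# posterior mean/variance at query rows by dense Gaussian conditioning,
# replicating the stated standardization arithmetic
dense_posterior_oracle <- function(X, y, hyper, Q, standardize = TRUE) {
  if (standardize) {
    center <- mean(y)
    v <- if (length(y) < 2) 0 else var(y)
    scl <- if (v < 1e-12) 1 else sqrt(v)
  } else {
    center <- 0; scl <- 1
  }
  ys <- (y - center) / scl
  M <- obs_cov_oracle(X, hyper)
  Minv <- solve(M)
  Kq <- kernel_matrix(hyper$kernel, Q, X)
  mu <- drop(Kq %*% Minv %*% ys)
  vv <- hyper$kernel$variance - diag(Kq %*% Minv %*% t(Kq))
  list(mean = center + scl * mu, variance = scl^2 * pmax(vv, 0))
}

# naive leave-one-out refit: hold out point i, condition on the rest by
# dense solves; predictive variance includes the observation noise
naive_loo_oracle <- function(X, y, hyper, standardize = TRUE) {
  if (standardize) {
    std <- standardize_observations(y)
  } else {
    std <- list(y = y, center = 0, scale = 1)
  }
  n <- length(y)
  Mfull <- kernel_matrix(hyper$kernel, X)
  diag(Mfull) <- diag(Mfull) + hyper$noise_variance
  mu <- s2 <- numeric(n)
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]
    Mi <- kernel_matrix(hyper$kernel, Xi)
    diag(Mi) <- diag(Mi) + hyper$noise_variance + base_jitter(Mfull)
    ki <- drop(kernel_matrix(hyper$kernel, X[i, , drop = FALSE], Xi))
    sol <- solve(Mi, std$y[-i])
    mu[i] <- sum(ki * sol)
    s2[i] <- hyper$kernel$variance - drop(t(ki) %*% solve(Mi, ki)) +
      hyper$noise_variance + base_jitter(Mfull)
  }
  list(mean = mu, variance = s2, y = std$y)
}

# draw one sample path of a zero-mean GP at the rows of X
sample_gp <- function(X, spec, noise_variance = 0) {
  K <- kernel_matrix(spec, X)
  diag(K) <- diag(K) + noise_variance + 1e-10
  drop(t(chol(K)) %*% rnorm(nrow(X)))
}

random_hyper <- function(family = sample(c("Exponential", "Matern32",
                                           "Matern52", "RBF"), 1)) {
  gp_hyperparameters(
    kernel_spec(family,
                length_scale = exp(runif(1, log(0.1), log(2))),
                variance = exp(runif(1, log(0.2), log(5)))),
    noise_variance = exp(runif(1, log(1e-4), log(0.1))))
}

random_training <- function(n, d) {
  list(X = matrix(runif(n * d), n, d), y = rnorm(n))
}
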