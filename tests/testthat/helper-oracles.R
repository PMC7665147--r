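# Independent oracles used across tests. These re-derive every quantity from
# first principles (direct complex summation, generic numerical optimization,
# plain Riemann sums) and share no code with the implementation paths they
# check.

# Brute-force windowed Fourier magnitude: direct complex summation per
# frequency, with the raised-cosine taper rebuilt inline.
stft_oracle <- function(vm, fs, freqs) {
  tau <- length(vm)
  u <- 0:(tau - 1)
  h <- 0.5 * (1 - cos(2 * pi * u / (tau - 1)))
  vapply(freqs, function(f) {
    Mod(sum(vm * h * exp(-2i * pi * f * u / fs)))
  }, numeric(1))
}

# Penalized least-squares objective of the scalar-on-function criterion and
# its gradient, for minimization by a generic optimizer.
pls_objective <- function(theta, y, X, W, LtL, lambda) {
  K <- ncol(X)
  p <- ncol(W)
  g <- theta[seq_len(K)]
  b <- theta[K + seq_len(p)]
  r <- y - as.numeric(X %*% g) - as.numeric(W %*% b)
  sum(r^2) + lambda * sum(b * as.numeric(LtL %*% b))
}

pls_gradient <- function(theta, y, X, W, LtL, lambda) {
  Xo <- cbind(X, W)
  K <- ncol(X)
  p <- ncol(W)
  r <- y - as.numeric(Xo %*% theta)
  pen <- c(rep(0, K), 2 * lambda * as.numeric(LtL %*% theta[K + seq_len(p)]))
  -2 * as.numeric(crossprod(Xo, r)) + pen
}

pls_minimize <- function(y, X, W, LtL, lambda) {
  theta0 <- rep(0, ncol(X) + ncol(W))
  opt <- stats::optim(theta0, pls_objective, pls_gradient,
                      y = y, X = X, W = W, LtL = LtL, lambda = lambda,
                      method = "BFGS",
                      control = list(maxit = 5000, reltol = 1e-16))
  opt$par
}

# Random small regression instance with a low-rank informative subspace.
random_small_instance <- function(N, p, K = 2) {
  X <- cbind(1, matrix(rnorm(N * (K - 1)), N, K - 1))
  W <- matrix(rnorm(N * p), N, p)
  m <- max(1L, p %/% 3L)
  Qb <- qr.Q(qr(matrix(rnorm(p * m), p, m)))
  op <- penalty_operator(tcrossprod(Qb), a = runif(1, 0.5, 3))
  y <- rnorm(N)
  list(y = y, X = X, W = W, op = op, lambda = exp(runif(1, -2, 2)))
}

# Small, fast cohort used where full study sizes are unnecessary.
quick_cohort <- function(n = 8, seed = 1, sigma_eps = 1, duration_s = 30,
                         beta_true = NULL, gamma_true = c(intercept = 70,
                                                          male = -1,
                                                          cadence = 2,
                                                          vmc = 3)) {
  grid <- order_grid()
  if (is.null(beta_true)) beta_true <- default_beta_true(grid)
  sp <- cohort_spec(
    n_subjects = n, seed = seed, sigma_eps = sigma_eps,
    beta_true = beta_true, gamma_true = gamma_true, grid = grid,
    gait_sampler = function() sample_gait_params(duration_s = duration_s))
  simulate_cohort(sp)
}
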