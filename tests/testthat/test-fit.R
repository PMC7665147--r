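test_that("design assembly joins by subject and applies the quadrature", {
  co <- quick_cohort(n = 6, seed = 21)
  ds <- assemble_design(co$features, co$covariates, co$y)
  expect_equal(dim(ds$X), c(6, 4))
  expect_equal(colnames(ds$X), c("intercept", "male", "cadence", "vmc"))
  expect_equal(dim(ds$W), c(6, 546))
  expect_equal(ds$delta_s, 0.01, tolerance = 1e-10)
  # rows of W are the spectra times the grid spacing
  expect_equal(ds$W[3, ], co$features[[3]]$spectrum * ds$delta_s)

  # missing features: error names the subject
  expect_error(
    assemble_design(co$features[-2], co$covariates, co$y), "subj002")
  expect_error(
    assemble_design(co$features, co$covariates, co$y[-1]), "length")

  # integral scaling can be disabled
  ds0 <- assemble_design(co$features, co$covariates, co$y,
                         scale_integral = FALSE)
  expect_equal(ds0$W, ds$W / ds$delta_s)
})

test_that("permuting subject order leaves the fit invariant", {
  co <- quick_cohort(n = 20, seed = 5, sigma_eps = 0.5)
  set.seed(99)
  perm <- sample(20)
  ds1 <- assemble_design(co$features, co$covariates, co$y)
  ds2 <- assemble_design(co$features[perm], co$covariates[perm, ],
                         co$y[perm])
  f1 <- fit_functional_model(ds1)
  f2 <- fit_functional_model(ds2)
  expect_equal(f1$gamma_hat, f2$gamma_hat, tolerance = 1e-6)
  expect_equal(f1$beta_hat, f2$beta_hat, tolerance = 1e-6)
  expect_equal(f1$lambda, f2$lambda, tolerance = 1e-6)
})

test_that("constant scalar covariates are dropped with a warning", {
  co <- quick_cohort(n = 5, seed = 2)
  co$covariates$male <- 1
  expect_warning(ds <- assemble_design(co$features, co$covariates, co$y),
                 "male")
  expect_false("male" %in% colnames(ds$X))
})

test_that("with a null functional block the fit reduces to OLS on X", {
  set.seed(30)
  N <- 25
  X <- cbind(1, rnorm(N), rbinom(N, 1, 0.5))
  y <- as.numeric(X %*% c(2, -1, 0.5) + rnorm(N, 0, 0.3))
  p <- 12
  W <- matrix(0, N, p)
  op <- penalty_operator(diag(p) * 0, a = 2)  # P_Q = 0: pure ridge at a^2
  ds <- list(y = y, X = X, W = W)
  fit <- fit_generalized_ridge(ds, op, lambda = 3.7)
  expect_equal(unname(fit$gamma_hat),
               unname(coef(lm.fit(X, y))), tolerance = 1e-10)
  expect_equal(fit$beta_hat, rep(0, p))
})

test_that("a = 1 reproduces the closed-form ridge estimate", {
  set.seed(31)
  N <- 15; p <- 40
  W <- matrix(rnorm(N * p), N, p)
  y <- rnorm(N)
  lambda <- 2.5
  op <- penalty_operator(projection(qr.Q(qr(matrix(rnorm(p * 4), p, 4)))),
                         a = 1)
  ds <- list(y = y, X = matrix(0, N, 0), W = W)
  fit <- fit_generalized_ridge(ds, op, lambda)
  closed <- solve(crossprod(W) + lambda * diag(p), crossprod(W, y))
  expect_lt(max(abs(fit$beta_hat - closed)) / max(abs(closed)), 1e-10)
})

test_that("closed-form solution matches a generic optimizer on the criterion", {
  set.seed(32)
  for (i in 1:5) {
    inst <- random_small_instance(N = sample(6:10, 1), p = sample(4:8, 1))
    ds <- list(y = inst$y, X = inst$X, W = inst$W)
    fit <- fit_generalized_ridge(ds, inst$op, inst$lambda)
    theta <- c(fit$gamma_hat, fit$beta_hat)
    theta_opt <- pls_minimize(inst$y, inst$X, inst$W, inst$op$LtL,
                              inst$lambda)
    expect_lt(max(abs(theta - theta_opt)) / max(abs(theta_opt)), 1e-6)
  }
})

test_that("lambda = 0 with p > N fails with a rank error", {
  set.seed(33)
  W <- matrix(rnorm(5 * 9), 5, 9)
  op <- penalty_operator(diag(9) * 0, a = 1)
  ds <- list(y = rnorm(5), X = matrix(0, 5, 0), W = W)
  expect_error(fit_generalized_ridge(ds, op, 0), "singular")
  expect_error(fit_generalized_ridge(ds, op, -1), "nonnegative")
  ds$y[2] <- NA
  expect_error(fit_generalized_ridge(ds, op, 1), "non-finite")
})

test_that("REML lambda equals the variance ratio and matches mgcv", {
  skip_if_not_installed("mgcv")
  set.seed(34)
  N <- 40; p <- 30
  W <- matrix(rnorm(N * p), N, p) %*% diag(exp(-seq(0, 2, length.out = p)))
  X <- cbind(1, rnorm(N))
  Qb <- qr.Q(qr(matrix(rnorm(p * 3), p, 3)))
  op <- penalty_operator(tcrossprod(Qb), a = 2)
  y <- as.numeric(X %*% c(1, 0.5) + W %*% (Qb %*% c(3, -2, 1)) +
                    rnorm(N, 0, 0.5))
  ds <- list(y = y, X = X, W = W)
  sel <- select_lambda_reml(ds, op)
  expect_equal(sel$lambda, sel$sigma_eps2 / sel$sigma_beta2)

  x2 <- X[, 2]
  g <- mgcv::gam(y ~ x2 + W, paraPen = list(W = list(op$LtL)),
                 method = "REML")
  expect_equal(sel$lambda, unname(g$sp), tolerance = 1e-4)
  expect_equal(sel$sigma_eps2, g$scale, tolerance = 1e-4)
  fit <- fit_generalized_ridge(ds, op, sel$lambda)
  expect_equal(unname(c(fit$gamma_hat, fit$beta_hat)), unname(coef(g)),
               tolerance = 1e-5)
})

test_that("REML shrinks beta away when there is no functional signal", {
  co <- quick_cohort(n = 30, seed = 41, sigma_eps = 1,
                     beta_true = rep(0, 546))
  ds <- assemble_design(co$features, co$covariates, co$y)
  fit <- suppressWarnings(fit_functional_model(ds))
  expect_gt(fit$lambda, 10)
  expect_lt(max(abs(fit$beta_hat)), 1)
  expect_length(fit$significant, 0)
})

test_that("shrinkage in the L-norm is monotone in lambda", {
  co <- quick_cohort(n = 12, seed = 43)
  ds <- assemble_design(co$features, co$covariates, co$y)
  op <- penalty_operator(projection(build_basis(ds$order_grid)), a = 2)
  norms <- vapply(c(0.001, 0.1, 10, 1000), function(lam) {
    f <- fit_generalized_ridge(ds, op, lam)
    sqrt(sum((op$L %*% f$beta_hat)^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("larger a shrinks the off-span component preferentially", {
  set.seed(44)
  N <- 30; p <- 40
  W <- matrix(rnorm(N * p), N, p)
  Qb <- qr.Q(qr(matrix(rnorm(p * 3), p, 3)))
  P <- tcrossprod(Qb)
  beta <- as.numeric(Qb %*% c(2, -1, 1)) + as.numeric((diag(p) - P) %*% rnorm(p))
  y <- as.numeric(W %*% beta + rnorm(N, 0, 0.2))
  ds <- list(y = y, X = matrix(0, N, 0), W = W)
  ratio <- vapply(c(1, 2, 8, 32), function(a) {
    f <- fit_generalized_ridge(ds, penalty_operator(P, a = a), lambda = 5)
    out <- sqrt(sum(((diag(p) - P) %*% f$beta_hat)^2))
    inn <- sqrt(sum((P %*% f$beta_hat)^2))
    out / inn
  }, numeric(1))
  expect_true(all(diff(ratio) < 0))
})

test_that("bands are symmetric around the estimate and respect the level", {
  co <- quick_cohort(n = 15, seed = 45)
  ds <- assemble_design(co$features, co$covariates, co$y)
  fit <- fit_functional_model(ds, level = 0.95)
  expect_true(all(fit$band_lower <= fit$beta_hat))
  expect_true(all(fit$beta_hat <= fit$band_upper))
  expect_equal(fit$band_upper - fit$beta_hat, fit$beta_hat - fit$band_lower)
  # wider level, wider band
  fit99 <- fit_functional_model(ds, level = 0.99)
  expect_true(all(fit99$band_upper - fit99$band_lower >=
                    fit$band_upper - fit$band_lower))
  # significant multiples live on the basis centers
  expect_true(all(fit$significant %in% fit$basis$centers))
})

test_that("sandwich bands are narrower than Bayesian bands here", {
  co <- quick_cohort(n = 15, seed = 46)
  ds <- assemble_design(co$features, co$covariates, co$y)
  basis <- build_basis(ds$order_grid)
  op <- penalty_operator(projection(basis), a = 2)
  sel <- select_lambda_reml(ds, op)
  fit <- fit_generalized_ridge(ds, op, sel$lambda)
  bb <- confidence_bands(fit, ds, sel$sigma_eps2, type = "bayesian")
  fb <- confidence_bands(fit, ds, sel$sigma_eps2, type = "sandwich")
  expect_true(all(fb$se_beta <= bb$se_beta + 1e-12))
})

test_that("significant_multiples reads the band at the nearest grid point", {
  g <- order_grid()
  beta <- rep(0, 546)
  lower <- rep(-1, 546)
  upper <- rep(1, 546)
  expect_length(significant_multiples(beta, lower, upper, g), 0)
  i25 <- which.min(abs(g - 2.5))
  lower[i25] <- 0.2; upper[i25] <- 0.8; beta[i25] <- 0.5
  expect_equal(significant_multiples(beta, lower, upper, g), 2.5)
  i40 <- which.min(abs(g - 4.0))
  lower[i40] <- -0.9; upper[i40] <- -0.1
  expect_equal(significant_multiples(beta, lower, upper, g), c(2.5, 4.0))
})
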