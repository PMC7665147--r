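#' Assemble the scalar-on-function design
#'
#' Joins subject-level spectral features with scalar covariates and the
#' response into the matrices of the functional linear model
#' \eqn{y = X\gamma + W\beta + \epsilon}. The scalar design is
#' (intercept, male, cadence, VMC); the functional design W holds one
#' scaled order-domain spectrum per row. By default each row of W is
#' multiplied by the grid spacing so that \eqn{W\beta} realizes the Riemann
#' sum for \eqn{\int W_i(s)\beta(s)\,ds} and the estimated coefficient
#' function is on the continuous (per order unit) scale.
#'
#' Scalar covariate columns with zero variance (other than the intercept)
#' are dropped with a warning rather than producing a singular fit.
#'
#' @param features List of `gait_features`, or the data frame from
#'   [features_to_df()].
#' @param covariates Data frame with columns `subject_id` and `male`
#'   (0/1 indicator).
#' @param y Numeric response vector aligned with `covariates$subject_id`.
#' @param scale_integral Multiply W by the grid spacing (default TRUE).
#' @return An object of class `design_set`: list with `y`, `X`, `W`,
#'   `order_grid`, `delta_s`, and `subject_id`.
#' @export
assemble_design <- function(features, covariates, y, scale_integral = TRUE) {
  fdf <- if (is.data.frame(features)) features else features_to_df(features)
  if (length(y) != nrow(covariates)) {
    stop("response length must match covariate rows", call. = FALSE)
  }
  ids <- as.character(covariates$subject_id)
  idx <- match(ids, fdf$subject_id)
  if (anyNA(idx)) {
    stop("no spectral features for subject(s): ",
         paste(ids[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  fdf <- fdf[idx, , drop = FALSE]
  spec_cols <- grep("^s_", names(fdf))
  grid <- as.numeric(sub("^s_", "", names(fdf)[spec_cols]))
  W <- as.matrix(fdf[, spec_cols, drop = FALSE])
  dimnames(W) <- NULL
  delta_s <- mean(diff(grid))
  if (scale_integral) W <- W * delta_s
  X <- cbind(intercept = 1,
             male = as.numeric(covariates$male),
             cadence = fdf$cadence,
             vmc = fdf$vmc)
  const <- apply(X[, -1L, drop = FALSE], 2L, function(v) diff(range(v)) == 0)
  if (any(const)) {
    warning("dropping constant scalar covariate(s): ",
            paste(colnames(X)[-1L][const], collapse = ", "), call. = FALSE)
    X <- X[, c(TRUE, !const), drop = FALSE]
  }
  structure(
    list(y = as.numeric(y), X = X, W = W, order_grid = grid,
         delta_s = delta_s, subject_id = ids),
    class = "design_set"
  )
}

penalty_block <- function(K, LtL) {
  p <- nrow(LtL)
  Pen <- matrix(0, K + p, K + p)
  Pen[(K + 1):(K + p), (K + 1):(K + p)] <- LtL
  Pen
}

#' Generalized ridge fit of the scalar-on-function model
#'
#' Solves the penalized least-squares criterion
#' \eqn{\|y - X\gamma - W\beta\|^2 + \lambda\|L\beta\|^2}
#' in closed form as
#' \eqn{(X_o^T X_o + \lambda L_o^T L_o)^{-1} X_o^T y} with
#' \eqn{X_o = [X\; W]} and the penalty acting only on the beta block.
#' With `a = 1` in the penalty operator this is an ordinary ridge estimate
#' of the coefficient function.
#'
#' @param ds A `design_set` from [assemble_design()]. `X` may have zero
#'   columns, in which case only the functional block is fitted.
#' @param op A `penalty_operator`.
#' @param lambda Nonnegative tuning parameter. `lambda = 0` requires
#'   \eqn{X_o^T X_o} to be invertible (generally false when p > N).
#' @return List with `gamma_hat` (named), `beta_hat` (length p), and the
#'   Cholesky factor `chol_A` of the penalized normal-equation matrix.
#' @export
fit_generalized_ridge <- function(ds, op, lambda) {
  if (!is.finite(lambda) || lambda < 0) {
    stop("lambda must be nonnegative and finite", call. = FALSE)
  }
  Xo <- cbind(ds$X, ds$W)
  if (!all(is.finite(Xo)) || !all(is.finite(ds$y))) {
    stop("non-finite values in design or response", call. = FALSE)
  }
  K <- ncol(ds$X)
  p <- ncol(ds$W)
  A <- crossprod(Xo) + lambda * penalty_block(K, op$LtL)
  R <- tryCatch(chol(A), error = function(e) {
    stop("penalized system is singular (lambda = ", lambda,
         "); with lambda = 0 this requires N >= K + p", call. = FALSE)
  })
  theta <- backsolve(R, forwardsolve(t(R), crossprod(Xo, ds$y)))
  gamma_hat <- if (K > 0) setNames(theta[seq_len(K)], colnames(ds$X)) else numeric(0)
  list(gamma_hat = gamma_hat,
       beta_hat = as.numeric(theta[K + seq_len(p)]),
       chol_A = R)
}

#' Select the tuning parameter by REML via the mixed-model equivalence
#'
#' Reparameterizing \eqn{b = L\beta} turns the penalized criterion into a
#' linear mixed model \eqn{y = X\gamma + Zb + \epsilon} with
#' \eqn{Z = W L^{-1}}, random coefficients \eqn{b \sim N(0, \sigma_\beta^2 I)}
#' and residuals \eqn{\epsilon \sim N(0, \sigma_\epsilon^2 I)}. The tuning
#' parameter is the variance ratio
#' \eqn{\lambda = \sigma_\epsilon^2 / \sigma_\beta^2}, estimated by
#' restricted maximum likelihood. The restricted likelihood is profiled over
#' \eqn{\sigma_\epsilon^2} and maximized over \eqn{\log\lambda} on
#' \eqn{[10^{-6}, 10^{6}]} by one-dimensional optimization; an estimate at
#' the upper boundary (vanishing \eqn{\sigma_\beta^2}) is returned with a
#' warning.
#'
#' @param ds A `design_set`.
#' @param op A `penalty_operator` (invertible for any a > 0).
#' @param lambda_range Search interval for lambda.
#' @return List with `lambda`, `sigma_eps2`, `sigma_beta2`, and the profiled
#'   restricted log-likelihood `reml` at the optimum.
#' @export
select_lambda_reml <- function(ds, op, lambda_range = c(1e-6, 1e6)) {
  Z <- ds$W %*% penalty_inverse(op)
  N <- length(ds$y)
  K <- ncol(ds$X)
  eg <- eigen(tcrossprod(Z), symmetric = TRUE)
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  yt <- crossprod(U, ds$y)
  Xt <- if (K > 0) crossprod(U, ds$X) else matrix(0, N, 0)

  neg_restricted_ll <- function(log_lambda) {
    lambda <- exp(log_lambda)
    v <- 1 + d / lambda           # eigenvalues of V = I + ZZ'/lambda
    Vi_y <- yt / v
    if (K > 0) {
      Vi_X <- Xt / v
      G <- crossprod(Xt, Vi_X)
      cG <- chol(G)
      bhat <- backsolve(cG, forwardsolve(t(cG), crossprod(Xt, Vi_y)))
      quad <- sum(yt * Vi_y) - sum(crossprod(Xt, Vi_y) * bhat)
      logdetG <- 2 * sum(log(diag(cG)))
    } else {
      quad <- sum(yt * Vi_y)
      logdetG <- 0
    }
    sigma2 <- quad / (N - K)
    0.5 * (sum(log(v)) + logdetG + (N - K) * log(sigma2) + (N - K))
  }

  opt <- stats::optimize(neg_restricted_ll,
                         interval = log(lambda_range), tol = 1e-8)
  lambda <- exp(opt$minimum)
  if (lambda >= lambda_range[2L] * 0.99) {
    warning("sigma_beta^2 estimated at ~0; lambda capped at ",
            format(lambda_range[2L]), call. = FALSE)
    lambda <- lambda_range[2L]
  }
  v <- 1 + d / lambda
  Vi_y <- yt / v
  if (K > 0) {
    Vi_X <- Xt / v
    G <- crossprod(Xt, Vi_X)
    bhat <- solve(G, crossprod(Xt, Vi_y))
    quad <- sum(yt * Vi_y) - sum(crossprod(Xt, Vi_y) * bhat)
  } else {
    quad <- sum(yt * Vi_y)
  }
  sigma_eps2 <- quad / (N - K)
  list(lambda = lambda,
       sigma_eps2 = sigma_eps2,
       sigma_beta2 = sigma_eps2 / lambda,
       reml = -opt$objective)
}

#' Pointwise confidence bands for the coefficient function
#'
#' Computes pointwise limits
#' \eqn{\tilde\beta(s_j) \pm z_{1-\alpha/2}\,\mathrm{SE}\{\tilde\beta(s_j)\}}
#' using the mixed-model (Bayesian ridge) covariance
#' \eqn{\hat\sigma_\epsilon^2 (X_o^T X_o + \lambda L_o^T L_o)^{-1}}, the
#' standard choice for penalized-spline bands. A frequentist sandwich
#' variant \eqn{\hat\sigma_\epsilon^2 A^{-1} X_o^T X_o A^{-1}} is available.
#' Uncertainty in the plugged-in lambda is ignored. Bands are pointwise
#' only; no simultaneous coverage is claimed.
#'
#' @param fit Result of [fit_generalized_ridge()].
#' @param ds The `design_set` used for the fit.
#' @param sigma_eps2 Residual variance estimate.
#' @param level Coverage level (default 0.95).
#' @param type `"bayesian"` (default) or `"sandwich"`.
#' @return List with `lower`, `upper` (length p), `se_beta`, `se_gamma`,
#'   and the coefficient covariance `cov_coef`.
#' @export
confidence_bands <- function(fit, ds, sigma_eps2, level = 0.95,
                             type = c("bayesian", "sandwich")) {
  type <- match.arg(type)
  K <- length(fit$gamma_hat)
  p <- length(fit$beta_hat)
  Ainv <- chol2inv(fit$chol_A)
  cov_coef <- if (type == "bayesian") {
    sigma_eps2 * Ainv
  } else {
    Xo <- cbind(ds$X, ds$W)
    sigma_eps2 * Ainv %*% crossprod(Xo) %*% Ainv
  }
  dg <- diag(cov_coef)
  if (any(dg < -1e-8 * max(abs(dg)))) {
    stop("coefficient covariance is not positive semidefinite", call. = FALSE)
  }
  dg <- pmax(dg, 0)
  z <- stats::qnorm(1 - (1 - level) / 2)
  se_beta <- sqrt(dg[K + seq_len(p)])
  list(lower = fit$beta_hat - z * se_beta,
       upper = fit$beta_hat + z * se_beta,
       se_beta = se_beta,
       se_gamma = sqrt(dg[seq_len(K)]),
       cov_coef = cov_coef)
}

#' Cadence multiples where the coefficient function is nonzero
#'
#' Evaluates the pointwise band at the grid point nearest each basis center
#' (multiples 0.5, 1.0, ..., 5.5 of the cadence by default) and returns the
#' multiples at which the band excludes zero.
#'
#' @param beta_hat,lower,upper Coefficient function and band on `grid`.
#' @param grid Order grid.
#' @param centers Basis-center multiples to examine.
#' @return Numeric vector, a subset of `centers` (possibly empty).
#' @export
significant_multiples <- function(beta_hat, lower, upper,
                                  grid = order_grid(),
                                  centers = seq(0.5, 5.5, by = 0.5)) {
  idx <- vapply(centers, function(ck) which.min(abs(grid - ck)), 0L)
  centers[lower[idx] > 0 | upper[idx] < 0]
}

#' Fit the full penalized functional linear model
#'
#' One-call wrapper: builds the Gaussian harmonic basis on the design's
#' order grid, forms the decomposition penalty, selects lambda by REML,
#' computes the generalized ridge fit and pointwise confidence bands, and
#' reports the cadence multiples at which the coefficient function differs
#' from zero.
#'
#' @param ds A `design_set` from [assemble_design()].
#' @param a Penalty contrast (default 2).
#' @param basis_sd Gaussian bell standard deviation (order units).
#' @param level Band coverage level.
#' @param lambda Optional fixed lambda; if `NULL` (default), selected by
#'   REML.
#' @param band_type Band covariance type, see [confidence_bands()].
#' @return An object of class `gait_fit`: list with `gamma_hat`, `beta_hat`,
#'   `band_lower`, `band_upper`, `se_gamma`, `lambda`, `sigma_eps2`,
#'   `sigma_beta2`, `significant`, `order_grid`, `basis`, and `penalty`.
#' @export
fit_functional_model <- function(ds, a = 2, basis_sd = 0.08, level = 0.95,
                                 lambda = NULL, band_type = "bayesian") {
  basis <- build_basis(ds$order_grid, sd = basis_sd)
  op <- penalty_operator(projection(basis), a = a)
  if (is.null(lambda)) {
    sel <- select_lambda_reml(ds, op)
  } else {
    fit0 <- fit_generalized_ridge(ds, op, lambda)
    rss <- sum((ds$y - cbind(ds$X, ds$W) %*%
                  c(fit0$gamma_hat, fit0$beta_hat))^2)
    sel <- list(lambda = lambda,
                sigma_eps2 = rss / max(1, length(ds$y) - ncol(ds$X)),
                sigma_beta2 = NA_real_, reml = NA_real_)
  }
  fit <- fit_generalized_ridge(ds, op, sel$lambda)
  bands <- confidence_bands(fit, ds, sel$sigma_eps2, level = level,
                            type = band_type)
  structure(
    list(gamma_hat = fit$gamma_hat,
         beta_hat = fit$beta_hat,
         band_lower = bands$lower,
         band_upper = bands$upper,
         se_gamma = setNames(bands$se_gamma, names(fit$gamma_hat)),
         lambda = sel$lambda,
         sigma_eps2 = sel$sigma_eps2,
         sigma_beta2 = sel$sigma_beta2,
         reml = sel$reml,
         level = level,
         significant = significant_multiples(fit$beta_hat, bands$lower,
                                             bands$upper, ds$order_grid,
                                             basis$centers),
         order_grid = ds$order_grid,
         basis = basis,
         penalty = op,
         n = length(ds$y)),
    class = "gait_fit"
  )
}

#' @export
print.gait_fit <- function(x, ...) {
  cat("Penalized scalar-on-function fit (decomposition penalty, a =",
      x$penalty$a, ")\n")
  cat(sprintf("  N = %d subjects, p = %d order-grid points\n",
              x$n, length(x$order_grid)))
  cat(sprintf("  lambda (REML) = %.4g  [sigma_eps^2 = %.4g, sigma_beta^2 = %.4g]\n",
              x$lambda, x$sigma_eps2, x$sigma_beta2))
  cat("  Scalar coefficients:\n")
  print(round(rbind(estimate = x$gamma_hat, se = x$se_gamma), 4))
  cat("  Cadence multiples with beta != 0 (pointwise ",
      x$level * 100, "% band): ",
      if (length(x$significant)) paste(x$significant, collapse = ", ")
      else "none", "\n", sep = "")
  invisible(x)
}

#' Plot the estimated coefficient function with pointwise bands
#'
#' @param x A `gait_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.gait_fit <- function(x, ...) {
  g <- x$order_grid
  ylim <- range(x$band_lower, x$band_upper, 0)
  graphics::plot(g, x$beta_hat, type = "n", ylim = ylim,
                 xlab = "Multiple of cadence", ylab = expression(tilde(beta)(s)),
                 ...)
  graphics::polygon(c(g, rev(g)), c(x$band_lower, rev(x$band_upper)),
                    col = "grey85", border = NA)
  graphics::abline(h = 0, lty = 2, col = "grey40")
  graphics::lines(g, x$beta_hat, lwd = 2, col = "steelblue4")
  invisible(x)
}
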