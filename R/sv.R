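# Heavy-tailed stochastic volatility with leverage. Latent log-volatilities
# x_n follow a diagonal AR(1); observed log-returns are
#   y_n = gamma_n^{-1/2} Lambda_n eps_n,  Lambda_n = diag(exp(x_n / 2)),
# with (eta_n, eps_n) jointly Gaussian with cross-covariance Sigma_rho
# (negative definite blocks induce leverage) and gamma_n ~ Gamma(nu/2, nu/2)
# an independent mixing sequence making the returns multivariate-t.
# Inference conditions on known gamma_{1:N} through the rescaled
# observations y^gamma_n = sqrt(gamma_n) y_n, under which
#   p(x_n | x_{n-1}, y^g_{n-1}) = N(A x_{n-1} + S_re z_{n-1}, Sigma_c),
#   p(y^g_n | x_n)              = N(0, Lambda_n Sigma_eps Lambda_n),
# where z_n = Lambda_n^{-1} y^g_n = exp(-x_n/2) * y^g_n,
# S_re = Sigma_rho Sigma_eps^{-1} and Sigma_c = Sigma_eta - S_re Sigma_rho.

#' Parameters of the stochastic-volatility model with leverage
#'
#' Validates positive definiteness of the joint noise covariance
#' `rbind(cbind(Sigma_eta, Sigma_rho), cbind(Sigma_rho, Sigma_eps))` and of
#' the conditional transition covariance, and precomputes the symmetric
#' factorizations used by the potential and gradient (per-evaluation cost is
#' then `O(d^2 N)`).
#'
#' @param d,N grid dimensions.
#' @param alpha length-`d` vector of AR coefficients, each in `[0, 1)`.
#' @param Sigma_eta,Sigma_eps `d x d` state / observation noise covariances.
#' @param Sigma_rho `d x d` cross-covariance block (leverage when negative
#'   definite).
#' @param nu degrees of freedom of the Gamma mixing law (integer `>= 1`).
#' @return list with class `sv_params`.
#' @export
sv_params <- function(d, N, alpha, Sigma_eta, Sigma_eps, Sigma_rho, nu) {
  d <- as.integer(d)
  if (length(alpha) == 1L) alpha <- rep(alpha, d)
  if (any(alpha < 0) || any(alpha >= 1)) stop("alpha entries must lie in [0, 1)")
  if (nu < 1) stop("nu must be a positive integer")
  joint <- rbind(cbind(Sigma_eta, Sigma_rho), cbind(Sigma_rho, Sigma_eps))
  if (max(abs(joint - t(joint))) > 1e-10) stop("joint noise covariance not symmetric")
  if (min(eigen(joint, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("joint noise covariance not positive definite")
  E <- solve(Sigma_eps)
  S_re <- Sigma_rho %*% E
  Sigma_c <- Sigma_eta - S_re %*% Sigma_rho
  Sigma_c <- (Sigma_c + t(Sigma_c)) / 2
  if (min(eigen(Sigma_c, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("conditional transition covariance not positive definite")
  # stationary covariance of the AR(1): S1_ij = Sigma_eta_ij / (1 - a_i a_j)
  S1 <- Sigma_eta / (1 - outer(alpha, alpha))
  structure(list(d = d, N = as.integer(N), alpha = alpha, A = diag(alpha, d),
                 Sigma_eta = Sigma_eta, Sigma_eps = Sigma_eps,
                 Sigma_rho = Sigma_rho, nu = nu,
                 E = E, S_re = S_re, Sigma_c = Sigma_c, C = solve(Sigma_c),
                 S1 = S1, P1 = solve(S1),
                 logdet_S1 = determinant(S1)$modulus[1L],
                 logdet_Sc = determinant(Sigma_c)$modulus[1L],
                 logdet_Se = determinant(Sigma_eps)$modulus[1L]),
            class = "sv_params")
}

#' Default synthetic-demo parameters for the SV model
#'
#' `alpha = 0.9`, `Sigma_eta = 0.1 * (0.3 + 0.7 I)` (equicorrelated),
#' `Sigma_eps` an AR(1)-correlation matrix `0.7^|i-j|`,
#' `Sigma_rho = -0.05 I` (leverage), `nu = 10`.
#'
#' @param d,N grid dimensions.
#' @return an [sv_params()] object.
#' @export
sv_default_params <- function(d, N) {
  idx <- seq_len(d)
  sv_params(d, N, alpha = rep(0.9, d),
            Sigma_eta = 0.1 * (matrix(0.3, d, d) + 0.7 * diag(d)),
            Sigma_eps = 0.7^abs(outer(idx, idx, "-")),
            Sigma_rho = -0.05 * diag(d), nu = 10L)
}

#' Bundle SV observations with their mixing variables
#'
#' @param y `d x N` observed log-returns.
#' @param gamma length-`N` positive mixing variables.
#' @return list with class `sv_dataset`: `y`, `gamma`, and the rescaled
#'   observations `y_gamma[, n] = sqrt(gamma[n]) * y[, n]`.
#' @export
sv_dataset <- function(y, gamma) {
  if (!is.matrix(y)) stop("y must be a matrix")
  if (length(gamma) != ncol(y)) stop("gamma must have one entry per time point")
  if (any(gamma <= 0)) stop("gamma must be strictly positive")
  structure(list(y = y, gamma = as.numeric(gamma),
                 y_gamma = sweep(y, 2L, sqrt(gamma), "*")),
            class = "sv_dataset")
}

#' Simulate the stochastic-volatility model
#'
#' `x_1` from the stationary law of the AR(1), `(eta_n, eps_n)` jointly
#' Gaussian, `gamma_n ~ Gamma(nu/2, nu/2)`,
#' `y_n = gamma_n^{-1/2} Lambda_n eps_n`.
#'
#' @param params an [sv_params()] object.
#' @param seed integer seed.
#' @return list with `x` (latent log-volatilities) and `data` (an
#'   [sv_dataset()]).
#' @export
simulate_sv <- function(params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- params$d; N <- params$N
  joint <- rbind(cbind(params$Sigma_eta, params$Sigma_rho),
                 cbind(params$Sigma_rho, params$Sigma_eps))
  Lj <- t(chol(joint))
  L1 <- t(chol(params$S1))
  x <- matrix(0, d, N); y <- matrix(0, d, N)
  gamma <- stats::rgamma(N, shape = params$nu / 2, rate = params$nu / 2)
  x[, 1L] <- L1 %*% stats::rnorm(d)
  noise <- Lj %*% matrix(stats::rnorm(2 * d * N), 2 * d, N)
  for (n in seq_len(N)) {
    eps_n <- noise[(d + 1L):(2L * d), n]
    y[, n] <- gamma[n]^(-0.5) * exp(x[, n] / 2) * eps_n
    if (n < N) x[, n + 1L] <- params$alpha * x[, n] + noise[1:d, n]
  }
  list(x = x, data = sv_dataset(y, gamma))
}

# z_n = exp(-x_n/2) * y^gamma_n for a range of columns
sv_z <- function(params, data, x, cols) {
  exp(-x[, cols, drop = FALSE] / 2) * data$y_gamma[, cols, drop = FALSE]
}

#' Potential of the SV model (conditional on the mixing variables)
#'
#' Negative log joint density of `x_{1:N}` and the rescaled observations
#' given `gamma_{1:N}`, including all x-dependent log-determinant terms
#' (`log det(Lambda_n Sigma_eps Lambda_n) = sum_k x_n^k + log det Sigma_eps`)
#' and all normalization constants.
#'
#' @param params an [sv_params()] object.
#' @param data an [sv_dataset()].
#' @param x `d x N` state matrix.
#' @return scalar potential value.
#' @export
sv_potential <- function(params, data, x) {
  d <- params$d; N <- params$N
  if (!is.matrix(x) || nrow(x) != d || ncol(x) != N) stop("x must be ", d, " x ", N)
  z <- sv_z(params, data, x, seq_len(N))
  # initial term
  u <- 0.5 * drop(crossprod(x[, 1L], params$P1 %*% x[, 1L])) +
    0.5 * params$logdet_S1 + d / 2 * log(2 * pi)
  # transitions n = 2..N
  if (N > 1L) {
    r <- x[, 2:N, drop = FALSE] - params$A %*% x[, 1:(N - 1L), drop = FALSE] -
      params$S_re %*% z[, 1:(N - 1L), drop = FALSE]
    u <- u + 0.5 * sum(r * (params$C %*% r)) +
      (N - 1) * (0.5 * params$logdet_Sc + d / 2 * log(2 * pi))
  }
  # observations n = 1..N
  u <- u + 0.5 * sum(z * (params$E %*% z)) + 0.5 * sum(x) +
    N * (0.5 * params$logdet_Se + d / 2 * log(2 * pi))
  u
}

#' Gradient of the SV potential
#'
#' Analytic gradient, including the chain-rule terms from the appearance of
#' `Lambda_{n-1}^{-1}` in the next step's transition mean and from the
#' x-dependent log-determinants.
#'
#' @inheritParams sv_potential
#' @return `d x N` matrix.
#' @export
sv_grad <- function(params, data, x) {
  sv_block_grad(params, data, x, 1L, params$d, 1L, params$N)
}

# Block-restricted gradient; touches only columns (l-1):(m+1).
sv_block_grad <- function(params, data, x, i, j, l, m) {
  d <- params$d; N <- params$N
  lo <- max(1L, l - 1L); hi <- min(N, m + 1L)
  xs <- x[, lo:hi, drop = FALSE]
  zs <- sv_z(params, data, x, lo:hi)
  nc <- hi - lo + 1L
  off <- function(n) n - lo + 1L                 # global column -> local
  g <- matrix(0, d, m - l + 1L)
  # residuals r_n for transitions with n in (lo+1):hi
  if (nc > 1L) {
    r <- xs[, 2:nc, drop = FALSE] - params$A %*% xs[, 1:(nc - 1L), drop = FALSE] -
      params$S_re %*% zs[, 1:(nc - 1L), drop = FALSE]
    Cr <- params$C %*% r                         # C r_n, columns index n = lo+1..hi
  }
  Ez <- params$E %*% zs
  for (n in l:m) {
    k <- n - l + 1L
    # observation: -1/2 z_n * (E z_n) + 1/2
    gc <- -0.5 * zs[, off(n)] * Ez[, off(n)] + 0.5
    if (n == 1L) gc <- gc + params$P1 %*% x[, 1L]
    if (n >= 2L) gc <- gc + Cr[, off(n) - 1L]    # d/dx_n of transition n
    if (n <= N - 1L) {                           # d/dx_n of transition n+1
      crn <- Cr[, off(n)]
      gc <- gc - params$alpha * crn +
        0.5 * zs[, off(n)] * drop(crossprod(params$S_re, crn))
    }
    g[, k] <- gc
  }
  g[i:j, , drop = FALSE]
}

#' SV model as a `potential_model`
#'
#' @inheritParams sv_potential
#' @return a non-quadratic [potential_model()]; lookahead rate bounds use a
#'   safety-inflated grid maximum.
#' @export
sv_model <- function(params, data) {
  force(params); force(data)
  potential_model(
    d = params$d, N = params$N,
    U = function(x) sv_potential(params, data, x),
    grad = function(x) sv_grad(params, data, x),
    block_grad = function(x, i, j, l, m) sv_block_grad(params, data, x, i, j, l, m),
    quadratic = FALSE, grad_dep_cols = 1L, name = "sv_leverage")
}
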