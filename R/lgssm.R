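# Linear-Gaussian AR(1) state-space model with a kernel-weighted
# autoregressive matrix:
#   x_1 ~ N(0, I_d),  x_n = A x_{n-1} + eta_n,  y_n = x_n + eps_n,
# eta, eps standard normal; A_ij = kern(i,j) / (psi + sum_l kern(i,l)) with
# kern(i,j) = exp(-|i-j|^2 / (2 sigma^2)). Serves both as a test bed (its
# smoothing distribution is exactly Gaussian, so a Kalman/RTS smoother gives
# ground truth) and as the package's default synthetic-data generator.

#' Kernel autoregressive matrix
#'
#' `A[i, j] = kern(i, j) / (psi + sum_l kern(i, l))` with a squared-exponential
#' kernel `kern(i, j) = exp(-|i - j|^2 / (2 sigma2))`. Entries are strictly
#' positive and every row sums to strictly less than one, so the latent AR(1)
#' process is stable.
#'
#' @param d spatial dimension.
#' @param sigma2 kernel bandwidth, `> 0`.
#' @param psi normalization offset, `> 0`.
#' @return a `d x d` matrix.
#' @export
build_ar_matrix <- function(d, sigma2, psi) {
  if (d < 1L) stop("d must be >= 1")
  if (!is.finite(sigma2) || sigma2 <= 0) stop("sigma2 must be positive")
  if (!is.finite(psi) || psi <= 0) stop("psi must be positive")
  idx <- seq_len(d)
  kern <- exp(-outer(idx, idx, function(i, j) (i - j)^2) / (2 * sigma2))
  sweep(kern, 1L, psi + rowSums(kern), "/")
}

#' Parameters of the linear-Gaussian AR(1) model
#'
#' @param d,N grid dimensions.
#' @param sigma2,psi kernel bandwidth and normalization offset of
#'   [build_ar_matrix()].
#' @return list with class `lgssm_params` carrying `d, N, sigma2, psi, A`.
#'   State and observation noise covariances are the identity.
#' @export
lgssm_params <- function(d, N, sigma2 = 5, psi = 0.1) {
  structure(list(d = as.integer(d), N = as.integer(N),
                 sigma2 = sigma2, psi = psi,
                 A = build_ar_matrix(d, sigma2, psi)),
            class = "lgssm_params")
}

check_lgssm_y <- function(params, y) {
  if (!is.matrix(y) || nrow(y) != params$d || ncol(y) != params$N)
    stop("y must be a ", params$d, " x ", params$N, " matrix")
  invisible(y)
}

#' Potential of the linear-Gaussian model
#'
#' `U(x) = -log p(x_{1:N}, y_{1:N})`, all Gaussian normalization constants
#' included, so that differences of `U` are exact log-density ratios.
#'
#' @param params an [lgssm_params()] object.
#' @param y `d x N` observation matrix.
#' @param x `d x N` state matrix.
#' @return scalar potential value.
#' @export
lgssm_potential <- function(params, y, x) {
  check_lgssm_y(params, y)
  if (!all(dim(x) == dim(y))) stop("x and y shapes differ")
  d <- params$d; N <- params$N; A <- params$A
  innov <- if (N > 1L) x[, 2:N, drop = FALSE] - A %*% x[, 1:(N - 1L), drop = FALSE] else NULL
  0.5 * sum(x[, 1L]^2) +
    (if (N > 1L) 0.5 * sum(innov^2) else 0) +
    0.5 * sum((x - y)^2) +
    N * d * log(2 * pi)
}

#' Gradient of the linear-Gaussian potential
#'
#' @inheritParams lgssm_potential
#' @return `d x N` matrix of partial derivatives.
#' @export
lgssm_grad <- function(params, y, x) {
  lgssm_block_grad(params, y, x, 1L, params$d, 1L, params$N)
}

# Block-restricted gradient: only columns (l-1):(m+1) of x enter the formula,
# so per-evaluation cost is O(d^2 * block width).
lgssm_block_grad <- function(params, y, x, i, j, l, m) {
  d <- params$d; N <- params$N; A <- params$A
  cols <- l:m
  g <- x[, cols, drop = FALSE] - y[, cols, drop = FALSE]      # observation term
  if (l == 1L) g[, 1L] <- g[, 1L] + x[, 1L]                   # x_1 prior
  lo <- max(l, 2L)
  if (lo <= m) {                                              # f(x_{n-1}, x_n), n in block
    inn <- x[, lo:m, drop = FALSE] - A %*% x[, (lo - 1L):(m - 1L), drop = FALSE]
    g[, (lo - l + 1L):(m - l + 1L)] <- g[, (lo - l + 1L):(m - l + 1L)] + inn
  }
  hi <- min(m, N - 1L)
  if (l <= hi) {                                              # f(x_n, x_{n+1}), n in block
    inn2 <- x[, (l + 1L):(hi + 1L), drop = FALSE] - A %*% x[, l:hi, drop = FALSE]
    g[, 1L:(hi - l + 1L)] <- g[, 1L:(hi - l + 1L)] - crossprod(A, inn2)
  }
  g[i:j, , drop = FALSE]
}

#' Simulate the linear-Gaussian model
#'
#' Draws `x_1 ~ N(0, I_d)`, `x_n = A x_{n-1} + eta_n`, `y_n = x_n + eps_n`.
#'
#' @param params an [lgssm_params()] object.
#' @param seed integer seed (the function calls [set.seed()]).
#' @return list with `x` (latent `d x N`) and `y` (observed `d x N`).
#' @export
simulate_lgssm <- function(params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- params$d; N <- params$N; A <- params$A
  x <- matrix(0, d, N)
  x[, 1L] <- stats::rnorm(d)
  if (N > 1L) for (n in 2:N) x[, n] <- A %*% x[, n - 1L] + stats::rnorm(d)
  y <- x + matrix(stats::rnorm(d * N), d, N)
  list(x = x, y = y)
}

#' Exact Kalman filter / RTS smoother for the linear-Gaussian model
#'
#' Computes the exact smoothing means and marginal covariances of
#' `p(x_n | y_{1:N})`; the reference against which the samplers' stationary
#' moments are validated.
#'
#' @inheritParams lgssm_potential
#' @return list with `means` (`d x N`) and `covs` (`d x d x N` array).
#' @export
kalman_rts_smoother <- function(params, y) {
  check_lgssm_y(params, y)
  d <- params$d; N <- params$N; A <- params$A
  I_d <- diag(d)
  mf <- matrix(0, d, N); Pf <- array(0, c(d, d, N))
  mp <- matrix(0, d, N); Pp <- array(0, c(d, d, N))
  m_pred <- rep(0, d); P_pred <- I_d
  for (n in seq_len(N)) {
    mp[, n] <- m_pred; Pp[, , n] <- P_pred
    S <- P_pred + I_d
    K <- t(solve(S, P_pred))                 # P_pred %*% S^{-1}, S symmetric
    mf[, n] <- m_pred + K %*% (y[, n] - m_pred)
    Pfn <- P_pred - K %*% P_pred
    Pf[, , n] <- (Pfn + t(Pfn)) / 2
    if (min(diag(Pf[, , n])) <= 0)
      stop("numerical conditioning failure: non-positive filtered variance")
    if (n < N) {
      m_pred <- drop(A %*% mf[, n])
      P_pred <- A %*% Pf[, , n] %*% t(A) + I_d
    }
  }
  ms <- matrix(0, d, N); Ps <- array(0, c(d, d, N))
  ms[, N] <- mf[, N]; Ps[, , N] <- Pf[, , N]
  if (N > 1L) for (n in (N - 1L):1L) {
    G <- t(solve(Pp[, , n + 1L], A %*% Pf[, , n]))   # Pf A' Pp^{-1}
    ms[, n] <- mf[, n] + G %*% (ms[, n + 1L] - mp[, n + 1L])
    Psn <- Pf[, , n] + G %*% (Ps[, , n + 1L] - Pp[, , n + 1L]) %*% t(G)
    Ps[, , n] <- (Psn + t(Psn)) / 2
  }
  list(means = ms, covs = Ps)
}

#' Exact joint-posterior draws for the linear-Gaussian model
#'
#' Samples `x_{1:N} | y_{1:N}` exactly via a Cholesky factor of the (dense)
#' joint precision matrix. Intended for moderate `d * N`; used e.g. to supply
#' exact stationary draws to [lemma1_empirical_check()].
#'
#' @inheritParams lgssm_potential
#' @param n_draws number of independent posterior draws.
#' @return list of `d x N` state matrices.
#' @export
lgssm_posterior_draws <- function(params, y, n_draws = 1L) {
  check_lgssm_y(params, y)
  d <- params$d; N <- params$N
  H <- lgssm_precision(params)
  R <- chol(H)                             # H = R'R
  mu <- backsolve(R, backsolve(R, as.vector(y), transpose = TRUE))
  lapply(seq_len(n_draws), function(s) {
    z <- stats::rnorm(d * N)
    matrix(mu + backsolve(R, z), d, N)
  })
}

# Dense joint precision of vec(x) (column-major: coordinate (k, n) at index
# (n-1)*d + k). Quadratic potential: U(x) = 1/2 vec(x)' H vec(x) - vec(y)' vec(x) + const.
lgssm_precision <- function(params) {
  d <- params$d; N <- params$N; A <- params$A
  I_d <- diag(d); AtA <- crossprod(A)
  H <- matrix(0, d * N, d * N)
  for (n in seq_len(N)) {
    rows <- ((n - 1L) * d + 1L):(n * d)
    Hnn <- I_d + I_d                       # prior-or-transition-in + observation
    if (n < N) Hnn <- Hnn + AtA
    H[rows, rows] <- Hnn
    if (n < N) {
      nxt <- (n * d + 1L):((n + 1L) * d)
      H[rows, nxt] <- -t(A)
      H[nxt, rows] <- -A
    }
  }
  H
}

#' Linear-Gaussian model as a `potential_model`
#'
#' @inheritParams lgssm_potential
#' @return a [potential_model()] (quadratic) ready for the samplers.
#' @export
lgssm_model <- function(params, y) {
  check_lgssm_y(params, y)
  force(params); force(y)
  potential_model(
    d = params$d, N = params$N,
    U = function(x) lgssm_potential(params, y, x),
    grad = function(x) lgssm_grad(params, y, x),
    block_grad = function(x, i, j, l, m) lgssm_block_grad(params, y, x, i, j, l, m),
    quadratic = TRUE, grad_dep_cols = 1L, name = "lgssm")
}
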