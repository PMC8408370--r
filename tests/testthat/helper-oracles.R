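# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: the dense Gaussian oracle builds the
# joint precision from the model equations directly, gradients are checked
# by finite differences, and blocking quantities by brute-force scans.

# Dense joint-Gaussian oracle for the linear-Gaussian AR(1) model:
# vec(x) ~ N(H^{-1} vec(y), H^{-1}) with H assembled term by term from
#   0.5||x_1||^2 + sum 0.5||x_n - A x_{n-1}||^2 + sum 0.5||x_n - y_n||^2.
dense_lgssm_oracle <- function(A, y) {
  d <- nrow(y); N <- ncol(y)
  H <- matrix(0, d * N, d * N)
  idx <- function(n) ((n - 1L) * d + 1L):(n * d)
  H[idx(1L), idx(1L)] <- diag(d)                      # x_1 prior
  if (N > 1L) for (n in 2:N) {
    H[idx(n), idx(n)] <- H[idx(n), idx(n)] + diag(d)  # innovation in x_n
    H[idx(n - 1L), idx(n - 1L)] <- H[idx(n - 1L), idx(n - 1L)] + t(A) %*% A
    H[idx(n - 1L), idx(n)] <- H[idx(n - 1L), idx(n)] - t(A)
    H[idx(n), idx(n - 1L)] <- H[idx(n), idx(n - 1L)] - A
  }
  for (n in 1:N)                                      # observations
    H[idx(n), idx(n)] <- H[idx(n), idx(n)] + diag(d)
  mean <- solve(H, as.vector(y))
  list(H = H, mean = matrix(mean, d, N), cov = solve(H),
       # negative log joint density including all constants
       U = function(x) {
         z <- as.vector(x)
         0.5 * drop(t(z) %*% H %*% z) - sum(z * as.vector(y)) +
           0.5 * sum(as.vector(y)^2) + N * d * log(2 * pi)
       })
}

# central finite-difference gradient of a scalar function of a matrix
fd_gradient <- function(f, x, h = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    e <- x * 0; e[i] <- h
    g[i] <- (f(x + e) - f(x - e)) / (2 * h)
  }
  g
}

# brute-force per-coordinate block membership count
brute_phi <- function(strategy) {
  phi <- matrix(0L, strategy$d, strategy$N)
  for (k in seq_len(strategy$d)) for (n in seq_len(strategy$N)) {
    cnt <- 0L
    for (r in seq_len(nrow(strategy$blocks))) {
      b <- strategy$blocks[r, ]
      if (k >= b[1L] && k <= b[2L] && n >= b[3L] && n <= b[4L]) cnt <- cnt + 1L
    }
    phi[k, n] <- cnt
  }
  phi
}

# brute-force pairwise disjointness test of a partition
brute_validate <- function(strategy, partition) {
  for (g in seq_along(partition$groups)) {
    ids <- partition$groups[[g]]
    if (length(ids) < 2L) next
    for (a in seq_along(ids)) for (b in seq_along(ids)) {
      if (a >= b) next
      b1 <- strategy$blocks[ids[a], ]; b2 <- strategy$blocks[ids[b], ]
      inter <- b1[1L] <= b2[2L] && b2[1L] <= b1[2L] &&
               b1[3L] <= b2[4L] && b2[3L] <= b1[4L]
      if (inter) return(FALSE)
    }
  }
  identical(sort(unlist(partition$groups)), seq_len(nrow(strategy$blocks)))
}

# independently coded stochastic-volatility potential without leverage
# (Sigma_rho = 0): plain AR(1) transitions plus observation terms
noleverage_sv_potential <- function(params, data, x) {
  d <- params$d; N <- params$N
  stopifnot(max(abs(params$Sigma_rho)) == 0)
  S1 <- params$Sigma_eta / (1 - outer(params$alpha, params$alpha))
  u <- 0.5 * drop(t(x[, 1L]) %*% solve(S1, x[, 1L])) +
    0.5 * determinant(S1)$modulus[1L] + d / 2 * log(2 * pi)
  if (N > 1L) for (n in 2:N) {
    r <- x[, n] - params$alpha * x[, n - 1L]
    u <- u + 0.5 * drop(t(r) %*% solve(params$Sigma_eta, r)) +
      0.5 * determinant(params$Sigma_eta)$modulus[1L] + d / 2 * log(2 * pi)
  }
  for (n in 1:N) {
    z <- exp(-x[, n] / 2) * data$y_gamma[, n]
    u <- u + 0.5 * drop(t(z) %*% solve(params$Sigma_eps, z)) +
      0.5 * sum(x[, n]) +
      0.5 * determinant(params$Sigma_eps)$modulus[1L] + d / 2 * log(2 * pi)
  }
  u
}

# reference single-block bouncy particle sampler, coded independently of the
# engine but consuming randomness in the same documented order (exponential
# proposal, selection uniform, acceptance uniform; refresh draws d*N normals
# then an exponential), so trajectories are comparable draw for draw
reference_single_block_bps <- function(model, config, x0, v0) {
  set.seed(config$seed)
  d <- model$d; N <- model$N
  x <- x0; v <- v0
  theta <- config$theta; gamma <- config$gamma_refresh
  horizon <- config$horizon; delta <- config$delta
  dd <- function(xx) sum(model$grad(xx) * v)
  mk_bound <- function() max(0, dd(x), dd(x + theta * v))
  t <- 0
  bound <- mk_bound(); window_end <- t + theta
  next_refresh <- if (gamma > 0) rexp(1) / gamma else Inf
  n_samp <- floor(horizon / delta + 1e-9)
  samples <- matrix(0, d * N, n_samp)
  k <- 1L
  repeat {
    tau_p <- if (bound > 0) t + rexp(1) / bound else Inf
    cand <- c(next_refresh, tau_p, window_end)
    ev <- which.min(cand); tau <- min(cand[ev], horizon)
    while (k <= n_samp && k * delta <= tau + 1e-12) {
      samples[, k] <- x + (k * delta - t) * v
      k <- k + 1L
    }
    x <- x + (tau - t) * v
    t <- tau
    if (t >= horizon) break
    if (ev == 1L) {
      v <- matrix(rnorm(d * N), d, N)
      bound <- mk_bound(); window_end <- t + theta
      next_refresh <- t + rexp(1) / gamma
    } else if (ev == 2L) {
      runif(1)                                  # block selection (single block)
      rate <- max(0, dd(x))
      if (runif(1) * bound < rate) {
        g <- model$grad(x)
        v <- v - (2 * sum(g * v) / sum(g * g)) * g
        bound <- mk_bound(); window_end <- t + theta
      }
    } else {
      bound <- mk_bound(); window_end <- t + theta
    }
  }
  samples
}

# small quadratic toy targets used by several engine tests
gaussian_model_2d <- function(rho = 0.6) {
  P <- solve(matrix(c(1, rho, rho, 1), 2, 2))
  potential_model(2, 1,
                  U = function(x) 0.5 * drop(t(x) %*% P %*% x),
                  grad = function(x) P %*% x,
                  quadratic = TRUE, grad_dep_cols = 0L, name = "gauss2d")
}

iid_gaussian_model <- function(d, N) {
  potential_model(d, N,
                  U = function(x) 0.5 * sum(x^2) + length(x) / 2 * log(2 * pi),
                  grad = function(x) x,
                  quadratic = TRUE, grad_dep_cols = 0L, name = "iid")
}

smoother_vars <- function(sm) {
  d <- dim(sm$covs)[1L]
  vapply(seq_len(dim(sm$covs)[3L]), function(n) diag(sm$covs[, , n]),
         numeric(d))
}
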