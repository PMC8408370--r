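# Diagnostics: turn piecewise-linear trajectories into discrete chains and
# compute mixing summaries (MSJD, running MSE against an exact reference,
# effective sample size, log-posterior trace).

#' Discretized chain container
#'
#' @param samples `(d*N) x n` matrix, one flattened state (column-major:
#'   coordinate `(k, n)` at row `(n-1)*d + k`) per sample time `j * delta`.
#' @param d,N grid dimensions.
#' @param delta thinning interval in sampler seconds.
#' @return object of class `bps_chain`.
#' @export
bps_chain <- function(samples, d, N, delta) {
  structure(list(samples = samples, d = as.integer(d), N = as.integer(N),
                 delta = delta,
                 times = delta * seq_len(ncol(samples))),
            class = "bps_chain")
}

#' @export
print.bps_chain <- function(x, ...) {
  cat(sprintf("bps_chain: %d samples of a %d x %d state, delta = %g\n",
              ncol(x$samples), x$d, x$N, x$delta))
  invisible(x)
}

#' Extract one coordinate's sample path
#'
#' @param chain a [bps_chain()].
#' @param k,n spatial and temporal indices of the coordinate.
#' @return numeric vector of samples.
#' @export
chain_coord <- function(chain, k, n) {
  chain$samples[(n - 1L) * chain$d + k, ]
}

#' Discretize a trajectory skeleton at a fixed interval
#'
#' Evaluates the piecewise-linear path at times `delta, 2 delta, ...` by
#' exact interpolation with slope `phi * v` between stored skeleton records
#' (no quadrature error); the final partial interval is dropped. Requires a
#' trajectory run with `store_skeleton = TRUE`.
#'
#' @param traj a `bps_trajectory` carrying a skeleton.
#' @param delta sampling interval `> 0`.
#' @return a [bps_chain()].
#' @export
discretize_trajectory <- function(traj, delta) {
  if (delta <= 0) stop("delta must be positive")
  sk <- traj$skeleton
  if (is.null(sk) || length(sk$times) == 0L) stop("trajectory carries no skeleton")
  d <- traj$d; N <- traj$N; phi <- traj$phi
  n_samp <- floor(traj$horizon / delta + 1e-9)
  samples <- matrix(0, d * N, n_samp)
  times <- sk$times
  seg <- 1L
  for (jj in seq_len(n_samp)) {
    tj <- jj * delta
    while (seg < length(times) && times[seg + 1L] <= tj + 1e-12) seg <- seg + 1L
    samples[, jj] <- sk$x[[seg]] + (tj - times[seg]) * (phi * sk$v[[seg]])
  }
  bps_chain(samples, d, N, delta)
}

#' Query a skeleton at arbitrary times
#'
#' @param traj a `bps_trajectory` carrying a skeleton.
#' @param at numeric vector of sampler times within `[0, horizon]`.
#' @return `(d*N) x length(at)` matrix of interpolated states.
#' @export
skeleton_state_at <- function(traj, at) {
  sk <- traj$skeleton
  if (is.null(sk)) stop("trajectory carries no skeleton")
  phi <- traj$phi
  out <- matrix(0, traj$d * traj$N, length(at))
  for (q in seq_along(at)) {
    seg <- findInterval(at[q] + 1e-12, sk$times)
    seg <- max(1L, min(seg, length(sk$times)))
    out[, q] <- sk$x[[seg]] + (at[q] - sk$times[seg]) * (phi * sk$v[[seg]])
  }
  out
}

#' Mean-square jump distance of one coordinate
#'
#' Average squared difference of successive thinned samples after discarding
#' an initial burn-in fraction. Doubling a coordinate's flow speed (as the
#' membership count `phi` does for shared coordinates) quadruples its MSJD.
#'
#' @param chain a [bps_chain()].
#' @param k,n coordinate indices.
#' @param burn_in fraction of initial samples discarded (default 25%).
#' @return non-negative scalar.
#' @export
mean_square_jump_distance <- function(chain, k, n, burn_in = 0.25) {
  z <- chain_coord(chain, k, n)
  z <- z[seq.int(floor(length(z) * burn_in) + 1L, length(z))]
  if (length(z) < 2L) stop("too few samples after burn-in")
  mean(diff(z)^2)
}

#' Running mean-square error against reference means
#'
#' For each sample count `j`, the squared error between the running
#' posterior-mean estimate over samples `1..j` and the exact reference,
#' averaged over all `d * N` coordinates.
#'
#' @param chain a [bps_chain()].
#' @param reference_means `d x N` matrix of exact smoothing means.
#' @param burn_in fraction of initial samples discarded before averaging.
#' @return numeric vector, one value per retained sample.
#' @export
mse_vs_reference <- function(chain, reference_means, burn_in = 0) {
  ref <- as.vector(reference_means)
  if (length(ref) != nrow(chain$samples)) stop("reference shape mismatch")
  sm <- chain$samples
  keep <- seq.int(floor(ncol(sm) * burn_in) + 1L, ncol(sm))
  sm <- sm[, keep, drop = FALSE]
  acc <- numeric(length(ref))
  out <- numeric(ncol(sm))
  for (jj in seq_len(ncol(sm))) {
    acc <- acc + sm[, jj]
    out[jj] <- mean((acc / jj - ref)^2)
  }
  out
}

#' Effective sample size (initial positive sequence estimator)
#'
#' `n / (1 + 2 sum rho_k)` with the autocorrelation sum truncated at the
#' first non-positive pair sum `rho_{2k} + rho_{2k+1}` (Geyer's initial
#' positive sequence), clipped to `(0, n]`.
#'
#' @param x numeric vector (one coordinate's chain), length `>= 50`.
#' @return scalar ESS; a constant chain yields 0 with a warning.
#' @export
ess <- function(x) {
  n <- length(x)
  if (n < 50L) stop("need at least 50 samples")
  if (stats::var(x) == 0) {
    warning("constant chain: ESS reported as 0")
    return(0)
  }
  lag_max <- min(n - 1L, 20000L)
  rho <- acf_fft(x, lag_max)
  # pair sums rho_{2k} + rho_{2k+1}, k = 0, 1, ... (rho_0 = 1)
  n_pairs <- floor((length(rho) - 1L) / 2L)
  acc <- 0
  for (k in seq_len(n_pairs)) {
    ps <- rho[2L * k] + rho[2L * k + 1L]       # lags 2k-1 and 2k
    if (ps <= 0) break
    acc <- acc + ps
  }
  min(n, max(n / (1 + 2 * acc), .Machine$double.eps))
}

# autocorrelation function via FFT (biased normalization, as stats::acf)
acf_fft <- function(x, lag_max) {
  n <- length(x)
  z <- x - mean(x)
  m <- stats::nextn(2L * n)
  f <- stats::fft(c(z, numeric(m - n)))
  ac <- Re(stats::fft(Mod(f)^2, inverse = TRUE))[seq_len(lag_max + 1L)] / m
  ac / ac[1L]
}

#' Log-posterior trace of a chain
#'
#' `-U` evaluated at each thinned sample.
#'
#' @param model a [potential_model()].
#' @param chain a [bps_chain()].
#' @return numeric vector.
#' @export
log_posterior_trace <- function(model, chain) {
  vapply(seq_len(ncol(chain$samples)), function(jj)
    -model$U(matrix(chain$samples[, jj], model$d, model$N)), 0)
}

#' Per-coordinate stationarity z-scores against exact reference moments
#'
#' For every coordinate, `(estimate - truth) / MCSE` for both the posterior
#' mean and the marginal variance. For a validation gate the MCSE should err
#' on the conservative side, so each moment's standard error is the larger
#' of two standard estimators: Geyer's initial-positive-sequence estimate
#' (`var * tau / n` with `tau = n / ESS`, applied to the chain for the mean
#' and to its centred squares for the variance) and the batch means estimate
#' (standard deviation of per-batch moments over `sqrt(n_batches)`). The two
#' have complementary failure modes — lag-window truncation versus batches
#' shorter than the slowest autocorrelation time.
#'
#' @param chain a [bps_chain()].
#' @param ref_means,ref_vars reference moments, `d x N` (or flattened).
#' @param burn_in fraction of initial samples discarded.
#' @param n_batches number of batches for the batch-means component.
#' @return list with vectors `z_mean` and `z_var` (length `d * N`).
#' @export
stationarity_zscores <- function(chain, ref_means, ref_vars, burn_in = 0.25,
                                 n_batches = 25L) {
  sm <- chain$samples
  keep <- seq.int(floor(ncol(sm) * burn_in) + 1L, ncol(sm))
  sm <- sm[, keep, drop = FALSE]
  ns <- ncol(sm)
  if (ns < 2L * n_batches) stop("too few samples for batch-means z-scores")
  batch <- rep(seq_len(n_batches), each = ceiling(ns / n_batches))[seq_len(ns)]
  p <- nrow(sm)
  z_mean <- numeric(p); z_var <- numeric(p)
  for (r in seq_len(p)) {
    z <- sm[r, ]
    m <- mean(z)
    se_ips <- sqrt(stats::var(z) / ess(z))
    se_bm <- stats::sd(tapply(z, batch, mean)) / sqrt(n_batches)
    z_mean[r] <- (m - ref_means[r]) / max(se_ips, se_bm)
    sq <- (z - m)^2
    se2_ips <- sqrt(stats::var(sq) / ess(sq))
    se2_bm <- stats::sd(tapply(sq, batch, mean)) / sqrt(n_batches)
    z_var[r] <- (mean(sq) - ref_vars[r]) / max(se2_ips, se2_bm)
  }
  list(z_mean = z_mean, z_var = z_var)
}
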