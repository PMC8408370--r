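# Partitioned (even-odd / four-clock) blocked bouncy particle sampler.
# Each sub-strategy kappa of a disjoint partition carries one clock whose
# rate is a lookahead bound on the *maximum* block rate inside kappa. At a
# kappa-event every block of kappa independently reflects with probability
# lambda_B / bound; because blocks within a sub-strategy are pairwise
# disjoint, the per-block updates commute and may run in parallel.

#' Maximum block rate within a sub-strategy
#'
#' @inheritParams block_rate
#' @param partition a [block_partition()] of the strategy.
#' @param kappa sub-strategy index (or label).
#' @return `max_B lambda_B(x, v)` over blocks of sub-strategy `kappa`.
#' @export
max_rate <- function(model, strategy, partition, x, v, kappa) {
  ids <- partition_group(partition, kappa)
  if (length(ids) == 0L) stop("empty sub-strategy")
  max(vapply(ids, function(b) block_rate(model, strategy, x, v, b), 0))
}

partition_group <- function(partition, kappa) {
  if (is.character(kappa)) kappa <- match(kappa, partition$labels)
  if (is.na(kappa) || kappa < 1L || kappa > length(partition$groups))
    stop("unknown sub-strategy")
  partition$groups[[kappa]]
}

#' Lookahead bound on a sub-strategy's maximum rate
#'
#' `max_B sup_{s in [0, theta]} lambda_B(x + s (phi * v), v)` over the blocks
#' of sub-strategy `kappa`: exact endpoint maxima for quadratic potentials,
#' safety-inflated grid maxima otherwise.
#'
#' @inheritParams max_rate
#' @param theta window length.
#' @param phi block-membership counts.
#' @param bound_grid,bound_safety see [sampler_config()].
#' @return non-negative bound dominating [max_rate()] along the window.
#' @export
global_bound <- function(model, strategy, partition, x, v, kappa, theta,
                         phi = compute_phi(strategy),
                         bound_grid = 16L, bound_safety = NULL) {
  ids <- partition_group(partition, kappa)
  max(vapply(ids, function(b)
    rate_bound_on_window(model, strategy, x, v, b, theta, phi = phi,
                         bound_grid = bound_grid,
                         bound_safety = bound_safety)$bound, 0))
}

#' Simultaneous velocity update of a whole sub-strategy
#'
#' Every block `B` of sub-strategy `kappa` independently reflects with
#' probability `lambda_B(x, v) / bound`. Per-block acceptance uniforms are
#' keyed by block index (drawn for all blocks up front), so the result is
#' bit-identical under any processing order — the contract that makes the
#' update parallelizable.
#'
#' @inheritParams max_rate
#' @param bound dominating rate (must be `>= max_rate` at `(x, v)`, else a
#'   bound-violation error is raised).
#' @param uniforms optional vector of acceptance uniforms, one per block of
#'   the sub-strategy in block-index order; drawn from the RNG when `NULL`.
#' @param process_order optional permutation of `seq_along(ids)` fixing the
#'   order in which blocks are processed (the result must not depend on it).
#' @return list with `v` (updated velocity) and `accepted` (logical vector
#'   per block of the sub-strategy, in block-index order).
#' @export
apply_partition_kernel <- function(model, strategy, partition, x, v, kappa,
                                   bound, uniforms = NULL, process_order = NULL) {
  ids <- partition_group(partition, kappa)
  if (is.null(uniforms)) uniforms <- stats::runif(length(ids))
  if (length(uniforms) != length(ids))
    stop("need one uniform per block of the sub-strategy")
  if (is.null(process_order)) process_order <- seq_along(ids)
  accepted <- logical(length(ids))
  for (pos in process_order) {
    b <- ids[pos]
    rate <- block_rate(model, strategy, x, v, b)
    if (rate > bound * (1 + 1e-9) + 1e-12)
      stop("rate bound violation in block ", b, ": rate ", rate,
           " exceeds sub-strategy bound ", bound)
    if (bound > 0 && uniforms[pos] * bound < rate) {
      v <- reflect_block(model, strategy, x, v, b)
      accepted[pos] <- TRUE
    }
  }
  list(v = v, accepted = accepted)
}

#' Simulate the partitioned (even-odd) blocked bouncy particle sampler
#'
#' One proposal clock per sub-strategy, at the lookahead bound of its
#' maximum block rate, plus the global refreshment clock. At a
#' `kappa`-proposal, [apply_partition_kernel()] updates all of `kappa`'s
#' blocks simultaneously. All sub-strategy bounds share a lookahead window
#' and are recomputed at window expiry, after any accepted reflection
#' (a velocity change alters the flow seen by every overlapping block), and
#' at refreshment.
#'
#' @inheritParams simulate_blocked_bps
#' @param partition a [block_partition()] passing [validate_partition()].
#' @return a `bps_trajectory`, as [simulate_blocked_bps()]; the event log's
#'   `block` column holds the ringing sub-strategy and `n_accepted` the
#'   number of blocks reflected at that event.
#' @export
simulate_even_odd_bps <- function(model, strategy, partition, config,
                                  x0 = NULL, v0 = NULL) {
  if (strategy$d != model$d || strategy$N != model$N)
    stop("strategy grid does not match the model")
  chk <- validate_partition(strategy, partition)
  if (!chk$valid) stop("partition fails the disjointness assumption")
  d <- model$d; N <- model$N
  set.seed(config$seed)
  x <- if (is.null(x0)) matrix(0, d, N) else check_state(model, x0, "x0")
  v <- if (is.null(v0)) matrix(stats::rnorm(d * N), d, N) else check_state(model, v0, "v0")
  phi <- compute_phi(strategy)
  w <- phi * v
  blocks <- strategy$blocks
  K <- length(partition$groups)
  theta <- config$theta
  safety <- resolve_safety(config, model)
  grid_s <- if (model$quadratic) c(0, theta)
            else seq(0, theta, length.out = max(2L, config$bound_grid))
  horizon <- config$horizon
  gamma <- config$gamma_refresh

  fidx <- lapply(seq_len(nrow(blocks)), function(b)
    as.vector(outer(blocks[b, 1L]:blocks[b, 2L],
                    (blocks[b, 3L]:blocks[b, 4L] - 1L) * d, "+")))
  dirderiv <- function(b, s) {
    xs <- if (s == 0) x else x + s * w
    bb <- blocks[b, ]
    sum(model$block_grad(xs, bb[1L], bb[2L], bb[3L], bb[4L]) *
          v[bb[1L]:bb[2L], bb[3L]:bb[4L], drop = FALSE])
  }
  quadratic <- model$quadratic
  nb_all <- nrow(blocks)
  counters <- c(proposals = 0, acceptances = 0, rejections = 0,
                refreshes = 0, expiries = 0, bound_recomputations = 0)
  Lam_k <- numeric(K)
  window_end <- 0
  window_t0 <- 0
  # affine rate coefficients per block (quadratic potentials): exact rate at
  # window time s is max(0, c0_b + c1_b * s)
  c0s <- numeric(nb_all); c1s <- numeric(nb_all)
  recompute_all <- function() {
    Gs <- lapply(grid_s, function(s) model$grad(if (s == 0) x else x + s * w))
    for (k in seq_len(K)) {
      ids <- partition$groups[[k]]
      Lam_k[k] <<- max(vapply(ids, function(b) {
        fi <- fidx[[b]]
        vb <- v[fi]
        vals <- vapply(Gs, function(G) sum(G[fi] * vb), 0)
        if (quadratic) {
          c0s[b] <<- vals[1L]
          c1s[b] <<- (vals[2L] - vals[1L]) / theta
        }
        max(0, vals)
      }, 0)) * safety
      if (config$audit && Lam_k[k] > 0) {
        for (s in stats::runif(8L, 0, theta)) {
          r <- max(vapply(ids, function(b) max(0, dirderiv(b, s)), 0))
          if (r > Lam_k[k] * (1 + 1e-9))
            stop("bound audit failure in sub-strategy ", k)
        }
      }
      counters["bound_recomputations"] <<- counters["bound_recomputations"] + length(ids)
    }
    window_t0 <<- t
    window_end <<- t + theta
  }
  block_rate_now <- function(b) {
    if (quadratic) max(0, c0s[b] + c1s[b] * (t - window_t0))
    else max(0, dirderiv(b, 0))
  }

  t <- 0
  recompute_all()
  next_refresh <- if (gamma > 0) stats::rexp(1L) / gamma else Inf
  ev_n <- 0L; ev_cap <- 1024L
  ev_time <- numeric(ev_cap); ev_kind <- integer(ev_cap)
  ev_block <- integer(ev_cap); ev_nacc <- integer(ev_cap)
  kind_names <- c("reflection", "refreshment", "bound-expiry", "proposal-rejected")
  delta <- config$delta
  n_samp <- if (is.null(delta)) 0L else floor(horizon / delta + 1e-9)
  samples <- if (n_samp > 0L) matrix(0, d * N, n_samp) else NULL
  samp_k <- 1L
  skel <- NULL
  if (config$store_skeleton) {
    skel <- new.env(parent = emptyenv())
    skel$times <- list(); skel$x <- list(); skel$v <- list()
  }
  push_skel <- function() {
    if (!is.null(skel)) {
      i <- length(skel$times) + 1L
      skel$times[[i]] <- t; skel$x[[i]] <- x; skel$v[[i]] <- v
    }
  }
  push_skel()
  emit_until <- function(tau) {
    while (samp_k <= n_samp && samp_k * delta <= tau + 1e-12) {
      samples[, samp_k] <<- x + (samp_k * delta - t) * w
      samp_k <<- samp_k + 1L
    }
  }

  repeat {
    Lam <- sum(Lam_k)
    tau_r <- next_refresh
    tau_p <- if (Lam > 0) t + stats::rexp(1L) / Lam else Inf
    cand <- c(tau_r, tau_p, window_end)  # tie priority: refresh < proposal < expiry
    which_ev <- which.min(cand)
    tau <- cand[which_ev]
    if (tau >= horizon) {
      if (!is.null(samples)) emit_until(horizon)
      x <- x + (horizon - t) * w
      t <- horizon
      break
    }
    if (!is.null(samples)) emit_until(tau)
    x <- x + (tau - t) * w
    t <- tau
    if (ev_n == ev_cap) {
      ev_cap <- ev_cap * 2L
      length(ev_time) <- ev_cap; length(ev_kind) <- ev_cap
      length(ev_block) <- ev_cap; length(ev_nacc) <- ev_cap
    }
    ev_n <- ev_n + 1L
    ev_time[ev_n] <- t
    if (which_ev == 1L) {                # refreshment
      v <- matrix(stats::rnorm(d * N), d, N)
      w <- phi * v
      recompute_all()
      counters["refreshes"] <- counters["refreshes"] + 1
      next_refresh <- t + (if (gamma > 0) stats::rexp(1L) / gamma else Inf)
      ev_kind[ev_n] <- 2L; ev_block[ev_n] <- NA_integer_; ev_nacc[ev_n] <- 0L
      push_skel()
    } else if (which_ev == 2L) {         # kappa proposal
      counters["proposals"] <- counters["proposals"] + 1
      u <- stats::runif(1L) * Lam
      k <- 1L; acc <- Lam_k[1L]
      while (acc < u && k < K) { k <- k + 1L; acc <- acc + Lam_k[k] }
      ids <- partition$groups[[k]]
      uniforms <- stats::runif(length(ids))
      n_acc <- 0L
      for (pos in seq_along(ids)) {
        b <- ids[pos]
        rate <- block_rate_now(b)
        if (rate > Lam_k[k] * (1 + 1e-9) + 1e-12)
          stop("rate bound violation in block ", b, " of sub-strategy ", k,
               ": true rate ", rate, " exceeds bound ", Lam_k[k])
        if (uniforms[pos] * Lam_k[k] < rate) {
          bb <- blocks[b, ]
          rws <- bb[1L]:bb[2L]; cls <- bb[3L]:bb[4L]
          g <- model$block_grad(x, bb[1L], bb[2L], bb[3L], bb[4L])
          g2 <- sum(g * g)
          if (g2 > 0) {
            vB <- v[rws, cls, drop = FALSE]
            v[rws, cls] <- vB - (2 * sum(g * vB) / g2) * g
            w[rws, cls] <- phi[rws, cls, drop = FALSE] * v[rws, cls, drop = FALSE]
            n_acc <- n_acc + 1L
          }
        }
      }
      if (n_acc > 0L) {
        recompute_all()
        counters["acceptances"] <- counters["acceptances"] + n_acc
        ev_kind[ev_n] <- 1L; ev_block[ev_n] <- k; ev_nacc[ev_n] <- n_acc
        push_skel()
      } else {
        counters["rejections"] <- counters["rejections"] + 1
        ev_kind[ev_n] <- 4L; ev_block[ev_n] <- k; ev_nacc[ev_n] <- 0L
      }
    } else {                             # window expiry
      recompute_all()
      counters["expiries"] <- counters["expiries"] + 1
      ev_kind[ev_n] <- 3L; ev_block[ev_n] <- NA_integer_; ev_nacc[ev_n] <- 0L
    }
  }
  push_skel()

  idx <- seq_len(ev_n)
  out <- list(model = model$name, sampler = "even_odd_bps",
              d = d, N = N, phi = phi,
              final_x = x, final_v = v, horizon = horizon,
              events = data.frame(time = ev_time[idx],
                                  kind = kind_names[ev_kind[idx]],
                                  block = ev_block[idx],
                                  n_accepted = ev_nacc[idx]),
              counters = counters,
              config = config, partition = partition)
  if (!is.null(skel))
    out$skeleton <- list(times = unlist(skel$times), x = skel$x, v = skel$v)
  if (!is.null(samples))
    out$chain <- bps_chain(samples[, seq_len(samp_k - 1L), drop = FALSE],
                           d = d, N = N, delta = delta)
  class(out) <- "bps_trajectory"
  out
}

#' Empirical check of the logarithmic growth of the maximum rate
#'
#' Under sub-exponential tails `P(lambda_B > s) <= 2 exp(-2 alpha s)` the
#' expected maximum rate over a sub-strategy grows at most like
#' `(2 e / alpha) log |B_kappa|`. This helper estimates
#' `E[max_B lambda_B]` under exact stationary draws for a growing number of
#' blocks and tabulates it against the analytic bound, with `alpha` fitted
#' from the pooled rate tail unless supplied.
#'
#' @param model_family `"iid"` (independent standard-normal coordinates,
#'   exact stationary draws by construction) or `"lgssm"` (exact posterior
#'   draws via [lgssm_posterior_draws()]).
#' @param block_counts vector of sub-strategy sizes `|B_kappa|` to probe.
#' @param alpha optional tail parameter; fitted from the data when `NULL`.
#' @param n_draws stationary draws per size.
#' @param width,overlap temporal block geometry.
#' @param d spatial dimension.
#' @return data.frame with one row per size: `n_blocks`, `mean_max_rate`,
#'   `alpha`, `bound` (`2e/alpha * log n_blocks`, `NA` for a single block),
#'   and `ok` (mean below bound).
#' @export
lemma1_empirical_check <- function(model_family = c("iid", "lgssm"),
                                   block_counts = c(4L, 8L, 16L, 32L, 64L),
                                   alpha = NULL, n_draws = 200L,
                                   width = 20L, overlap = 10L, d = 1L) {
  model_family <- match.arg(model_family)
  stride <- width - overlap
  res <- lapply(block_counts, function(m) {
    nb <- 2L * m                        # so the odd sub-strategy has m blocks
    N <- stride * (nb - 1L) + width
    strat <- make_temporal_strategy(d, N, width, overlap)
    stopifnot(nrow(strat$blocks) == nb)
    part <- even_odd_partition(strat)
    ids <- partition_group(part, "odd")
    if (model_family == "iid") {
      model <- potential_model(d, N,
                               U = function(x) 0.5 * sum(x^2) + length(x) / 2 * log(2 * pi),
                               grad = function(x) x, quadratic = TRUE,
                               grad_dep_cols = 0L, name = "iid_gaussian")
      draw_x <- function() matrix(stats::rnorm(d * N), d, N)
    } else {
      params <- lgssm_params(d, N)
      y <- simulate_lgssm(params)$y
      model <- lgssm_model(params, y)
      draws <- lgssm_posterior_draws(params, y, n_draws)
      di <- 0L
      draw_x <- function() { di <<- di + 1L; draws[[di]] }
    }
    rates <- matrix(0, n_draws, length(ids))
    for (s in seq_len(n_draws)) {
      x <- draw_x()
      v <- matrix(stats::rnorm(d * N), d, N)
      rates[s, ] <- vapply(ids, function(b) block_rate(model, strat, x, v, b), 0)
    }
    list(n_blocks = m, max_rates = apply(rates, 1L, max), all_rates = as.vector(rates))
  })
  pooled <- unlist(lapply(res, `[[`, "all_rates"))
  if (is.null(alpha)) alpha <- fit_rate_tail_alpha(pooled)
  out <- do.call(rbind, lapply(res, function(r) {
    bound <- if (r$n_blocks > 1L) 2 * exp(1) / alpha * log(r$n_blocks) else NA_real_
    data.frame(n_blocks = r$n_blocks, mean_max_rate = mean(r$max_rates),
               alpha = alpha, bound = bound,
               ok = if (is.na(bound)) NA else mean(r$max_rates) <= bound)
  }))
  rownames(out) <- NULL
  out
}

# Fit alpha in P(lambda > s) <= 2 exp(-2 alpha s) by least squares on the
# log empirical survival function over the upper tail of the positive rates.
fit_rate_tail_alpha <- function(rates) {
  pos <- rates[rates > 0]
  if (length(pos) < 50L) stop("too few positive rates to fit a tail")
  qs <- stats::quantile(pos, seq(0.5, 0.99, by = 0.01))
  surv <- vapply(qs, function(s) mean(rates > s), 0)
  fit <- stats::lm(log(surv) ~ qs)
  alpha <- -unname(stats::coef(fit)[2L]) / 2
  if (!is.finite(alpha) || alpha <= 0) stop("tail fit failed")
  alpha
}
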