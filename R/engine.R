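# Event-driven core: blocked bouncy particle sampler with Poisson thinning.
#
# The state (x, v) flows as x(t) = x + t * (phi * v) between events. Each
# block B carries an inhomogeneous Poisson clock with rate
#   lambda_B(x, v) = max(0, <grad_B U(x), v_B>_F),
# simulated by thinning against a piecewise-constant lookahead bound valid
# for a window of length theta. At an accepted event the velocity submatrix
# v_B reflects in the hyperplane orthogonal to the block gradient; an
# independent homogeneous clock with rate gamma refreshes the whole velocity
# from its N(0,1) stationary law.

#' Sampler configuration
#'
#' @param horizon total sampler time `T`.
#' @param seed integer seed; all randomness in a run derives from it.
#' @param gamma_refresh velocity refreshment rate `gamma >= 0` (events per
#'   unit sampler time).
#' @param theta lookahead window length `> 0` over which rate bounds are
#'   valid before recomputation.
#' @param delta optional thinning interval: when set, the trajectory is
#'   discretized on the fly at times `delta, 2 delta, ...`.
#' @param bound_safety multiplicative inflation `>= 1` applied to
#'   grid-estimated bounds; `NULL` resolves to 1 for quadratic potentials
#'   (endpoint bounds are exact) and 1.1 otherwise.
#' @param bound_grid number of equispaced evaluation points per lookahead
#'   window for non-quadratic potentials.
#' @param store_skeleton keep the full `(time, x, v)` record at every
#'   velocity change (memory grows with the number of events).
#' @param audit audit every freshly computed bound against the true rate at
#'   8 random interior points of its window (test mode; slows sampling).
#' @return list with class `sampler_config`.
#' @export
sampler_config <- function(horizon, seed = 1L, gamma_refresh = 0.1, theta = 1,
                           delta = NULL, bound_safety = NULL, bound_grid = 16L,
                           store_skeleton = FALSE, audit = FALSE) {
  if (horizon <= 0) stop("horizon must be positive")
  if (theta <= 0) stop("theta must be positive")
  if (gamma_refresh < 0) stop("gamma_refresh must be >= 0")
  if (!is.null(bound_safety) && bound_safety < 1) stop("bound_safety must be >= 1")
  structure(list(horizon = horizon, seed = as.integer(seed),
                 gamma_refresh = gamma_refresh, theta = theta, delta = delta,
                 bound_safety = bound_safety, bound_grid = as.integer(bound_grid),
                 store_skeleton = isTRUE(store_skeleton), audit = isTRUE(audit)),
            class = "sampler_config")
}

resolve_safety <- function(config, model) {
  if (!is.null(config$bound_safety)) config$bound_safety
  else if (model$quadratic) 1 else 1.1
}

#' Event rate of a block
#'
#' `lambda_B(x, v) = max(0, <grad_B U(x), v_B>_F)`: the positive part of the
#' directional derivative of the potential along the velocity, restricted to
#' the block.
#'
#' @param model a [potential_model()].
#' @param strategy a [blocking_strategy()].
#' @param x,v `d x N` state and velocity matrices.
#' @param block_index block whose rate to evaluate.
#' @return non-negative scalar.
#' @export
block_rate <- function(model, strategy, x, v, block_index) {
  b <- strategy$blocks[block_index, ]
  g <- model$block_grad(x, b[1L], b[2L], b[3L], b[4L])
  max(0, sum(g * v[b[1L]:b[2L], b[3L]:b[4L], drop = FALSE]))
}

#' Reflect a block's velocity in the gradient hyperplane
#'
#' `v_B <- v_B - 2 <grad_B U(x), v_B>_F / ||grad_B U(x)||_F^2 * grad_B U(x)`;
#' components outside the block are unchanged. The map is an involution and
#' preserves `||v_B||_F`. A zero block gradient leaves `v` unchanged (the
#' corresponding event rate is zero, so such a reflection is never accepted).
#'
#' @inheritParams block_rate
#' @return the full velocity matrix with the block's submatrix reflected.
#' @export
reflect_block <- function(model, strategy, x, v, block_index) {
  b <- strategy$blocks[block_index, ]
  rows <- b[1L]:b[2L]; cols <- b[3L]:b[4L]
  g <- model$block_grad(x, b[1L], b[2L], b[3L], b[4L])
  g2 <- sum(g * g)
  if (g2 == 0) return(v)
  vB <- v[rows, cols, drop = FALSE]
  v[rows, cols] <- vB - (2 * sum(g * vB) / g2) * g
  v
}

#' Resample the full velocity from its stationary law
#'
#' Every component independently `N(0, 1)`, drawn from the current RNG
#' stream.
#'
#' @param v velocity matrix (defines the shape of the draw).
#' @return matrix of the same shape with i.i.d. standard-normal entries.
#' @export
refresh_velocity <- function(v) {
  matrix(stats::rnorm(length(v)), nrow(v), ncol(v))
}

#' Lookahead rate bound for one block
#'
#' Upper bound on `lambda_B` along the deterministic flow
#' `s -> x + s * (phi * v)` for `s` in `[0, theta]`. The directional
#' derivative is affine in `s` for quadratic potentials, so the bound is the
#' exact maximum over the endpoints; otherwise it is the maximum over
#' `bound_grid` equispaced points, inflated by `bound_safety`.
#'
#' @inheritParams block_rate
#' @param theta window length.
#' @param phi block-membership counts (defaults to [compute_phi()]).
#' @param bound_grid,bound_safety see [sampler_config()].
#' @return list with `bound` and `valid_for = theta` (window length).
#' @export
rate_bound_on_window <- function(model, strategy, x, v, block_index, theta,
                                 phi = compute_phi(strategy),
                                 bound_grid = 16L, bound_safety = NULL) {
  safety <- if (is.null(bound_safety)) (if (model$quadratic) 1 else 1.1) else bound_safety
  b <- strategy$blocks[block_index, ]
  rows <- b[1L]:b[2L]; cols <- b[3L]:b[4L]
  w <- phi * v
  vB <- v[rows, cols, drop = FALSE]
  dd <- function(s) {
    xs <- if (s == 0) x else x + s * w
    sum(model$block_grad(xs, b[1L], b[2L], b[3L], b[4L]) * vB)
  }
  grid <- if (model$quadratic) c(0, theta)
          else seq(0, theta, length.out = max(2L, bound_grid))
  bound <- max(0, vapply(grid, dd, 0)) * safety
  list(bound = bound, valid_for = theta)
}

# Blocks whose lookahead bound is invalidated by a velocity change inside
# block b. The bound of B' tracks grad_{B'} U along the flow, which (for a
# Markov model) depends on x at columns (l'-dep):(m'+dep) across all rows;
# a reflection in b changes the flow exactly on b's rectangle. The resulting
# set is a superset of the rectangle-intersection neighborhood N(b).
invalidation_list <- function(strategy, dep_cols) {
  b <- strategy$blocks
  nb <- nrow(b)
  if (!is.finite(dep_cols)) return(lapply(seq_len(nb), function(z) seq_len(nb)))
  lapply(seq_len(nb), function(a) {
    which(b[, "l"] - dep_cols <= b[a, "m"] & b[, "m"] + dep_cols >= b[a, "l"])
  })
}

model_dep_cols <- function(model) {
  dc <- model$grad_dep_cols
  if (is.null(dc)) Inf else dc
}

#' Simulate the blocked bouncy particle sampler
#'
#' Runs the event loop until `config$horizon`: proposals from the
#' superposition of per-block bounding processes, block selection
#' proportional to the bounds, thinning acceptance with probability
#' `lambda_B / bar_lambda_B`, reflection of the accepted block's velocity,
#' window-based bound recomputation, and full velocity refreshment at rate
#' `gamma`. A proposal whose true rate exceeds its bound raises a hard error
#' naming the block (never silently accepted). Deterministic given
#' `config$seed`.
#'
#' @param model a [potential_model()].
#' @param strategy a [blocking_strategy()] covering the model's grid.
#' @param config a [sampler_config()].
#' @param x0,v0 initial state and velocity; defaults: zero matrix and an
#'   i.i.d. `N(0,1)` draw.
#' @return object of class `bps_trajectory`: final state, event-log
#'   data.frame, counters, optionally the skeleton, and (when
#'   `config$delta` is set) the discretized chain as a `bps_chain`.
#' @export
simulate_blocked_bps <- function(model, strategy, config, x0 = NULL, v0 = NULL) {
  if (strategy$d != model$d || strategy$N != model$N)
    stop("strategy grid does not match the model")
  d <- model$d; N <- model$N
  set.seed(config$seed)
  x <- if (is.null(x0)) matrix(0, d, N) else check_state(model, x0, "x0")
  v <- if (is.null(v0)) matrix(stats::rnorm(d * N), d, N) else check_state(model, v0, "v0")
  phi <- compute_phi(strategy)
  w <- phi * v
  blocks <- strategy$blocks; nb <- nrow(blocks)
  rows <- lapply(seq_len(nb), function(b) blocks[b, 1L]:blocks[b, 2L])
  cols <- lapply(seq_len(nb), function(b) blocks[b, 3L]:blocks[b, 4L])
  inval <- invalidation_list(strategy, model_dep_cols(model))
  theta <- config$theta
  safety <- resolve_safety(config, model)
  grid_s <- if (model$quadratic) c(0, theta)
            else seq(0, theta, length.out = max(2L, config$bound_grid))
  horizon <- config$horizon
  gamma <- config$gamma_refresh

  # flattened indices of each block into a d x N matrix, for fast inner
  # products G[idx] . v[idx]
  fidx <- lapply(seq_len(nb), function(b)
    as.vector(outer(rows[[b]], (cols[[b]] - 1L) * d, "+")))
  dirderiv <- function(b, s) {
    xs <- if (s == 0) x else x + s * w
    sum(model$block_grad(xs, blocks[b, 1L], blocks[b, 2L], blocks[b, 3L], blocks[b, 4L]) *
          v[rows[[b]], cols[[b]], drop = FALSE])
  }
  quadratic <- model$quadratic
  audit <- config$audit
  counters <- c(proposals = 0, acceptances = 0, rejections = 0,
                refreshes = 0, expiries = 0, bound_recomputations = 0)
  bounds <- numeric(nb); expiry <- numeric(nb)
  # For quadratic potentials the directional derivative of U along the flow
  # is affine in elapsed window time: r_b(s) = c0_b + c1_b * s. The
  # coefficients are cached at bound computation so that proposal-time rates
  # need no further gradient evaluations (exact, not an approximation).
  c0s <- numeric(nb); c1s <- numeric(nb); t0s <- numeric(nb)
  recompute <- function(idx) {
    nk <- length(idx)
    if (quadratic) {
      if (nk > 2L) {
        G0 <- model$grad(x)
        G1 <- model$grad(x + theta * w)
        for (b in idx) {
          fi <- fidx[[b]]
          vb <- v[fi]
          s0 <- sum(G0[fi] * vb); s1 <- sum(G1[fi] * vb)
          c0s[b] <<- s0; c1s[b] <<- (s1 - s0) / theta; t0s[b] <<- t
          bounds[b] <<- max(0, s0, s1) * safety
          expiry[b] <<- t + theta
        }
      } else {
        for (b in idx) {
          s0 <- dirderiv(b, 0); s1 <- dirderiv(b, theta)
          c0s[b] <<- s0; c1s[b] <<- (s1 - s0) / theta; t0s[b] <<- t
          bounds[b] <<- max(0, s0, s1) * safety
          expiry[b] <<- t + theta
        }
      }
    } else {
      Gs <- lapply(grid_s, function(s) model$grad(if (s == 0) x else x + s * w))
      for (b in idx) {
        fi <- fidx[[b]]
        vb <- v[fi]
        bounds[b] <<- max(0, vapply(Gs, function(G) sum(G[fi] * vb), 0)) * safety
        expiry[b] <<- t + theta
      }
    }
    if (audit) {
      for (b in idx) {
        if (bounds[b] <= 0) next
        for (s in stats::runif(8L, 0, theta)) {
          r <- max(0, dirderiv(b, s))
          if (r > bounds[b] * (1 + 1e-9))
            stop("bound audit failure in block ", b, ": rate ", r,
                 " exceeds bound ", bounds[b], " inside window")
        }
      }
    }
    counters["bound_recomputations"] <<- counters["bound_recomputations"] + nk
  }

  t <- 0
  recompute(seq_len(nb))
  next_refresh <- if (gamma > 0) stats::rexp(1L) / gamma else Inf
  # event log: local growable parallel vectors (appended in the loop body so
  # writes stay in place)
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
    Lam <- sum(bounds)
    tau_r <- next_refresh
    tau_p <- if (Lam > 0) t + stats::rexp(1L) / Lam else Inf
    tau_e <- min(expiry)
    cand <- c(tau_r, tau_p, tau_e)       # tie priority: refresh < proposal < expiry
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
      recompute(seq_len(nb))
      counters["refreshes"] <- counters["refreshes"] + 1
      next_refresh <- t + (if (gamma > 0) stats::rexp(1L) / gamma else Inf)
      ev_kind[ev_n] <- 2L; ev_block[ev_n] <- NA_integer_; ev_nacc[ev_n] <- 0L
      push_skel()
    } else if (which_ev == 2L) {         # thinning proposal
      counters["proposals"] <- counters["proposals"] + 1
      u <- stats::runif(1L) * Lam
      b <- 1L; acc <- bounds[1L]
      while (acc < u && b < nb) { b <- b + 1L; acc <- acc + bounds[b] }
      rate <- if (quadratic) max(0, c0s[b] + c1s[b] * (t - t0s[b]))
            else max(0, dirderiv(b, 0))
      if (rate > bounds[b] * (1 + 1e-9) + 1e-12)
        stop("rate bound violation in block ", b, ": true rate ", rate,
             " exceeds bound ", bounds[b], " (window ending ", expiry[b], ")")
      if (stats::runif(1L) * bounds[b] < rate) {
        g <- model$block_grad(x, blocks[b, 1L], blocks[b, 2L], blocks[b, 3L], blocks[b, 4L])
        g2 <- sum(g * g)
        if (g2 > 0) {
          vB <- v[rows[[b]], cols[[b]], drop = FALSE]
          v[rows[[b]], cols[[b]]] <- vB - (2 * sum(g * vB) / g2) * g
          w[rows[[b]], cols[[b]]] <- phi[rows[[b]], cols[[b]], drop = FALSE] *
            v[rows[[b]], cols[[b]], drop = FALSE]
          recompute(inval[[b]])
        }
        counters["acceptances"] <- counters["acceptances"] + 1
        ev_kind[ev_n] <- 1L; ev_block[ev_n] <- b; ev_nacc[ev_n] <- 1L
        push_skel()
      } else {
        counters["rejections"] <- counters["rejections"] + 1
        ev_kind[ev_n] <- 4L; ev_block[ev_n] <- b; ev_nacc[ev_n] <- 0L
      }
    } else {                             # bound expiry
      stale <- which(expiry <= t + 1e-12)
      recompute(stale)
      counters["expiries"] <- counters["expiries"] + 1
      ev_kind[ev_n] <- 3L; ev_block[ev_n] <- NA_integer_; ev_nacc[ev_n] <- 0L
    }
  }
  push_skel()

  idx <- seq_len(ev_n)
  out <- list(model = model$name, sampler = "blocked_bps",
              d = d, N = N, phi = phi,
              final_x = x, final_v = v, horizon = horizon,
              events = data.frame(time = ev_time[idx],
                                  kind = kind_names[ev_kind[idx]],
                                  block = ev_block[idx],
                                  n_accepted = ev_nacc[idx]),
              counters = counters,
              config = config)
  if (!is.null(skel))
    out$skeleton <- list(times = unlist(skel$times), x = skel$x, v = skel$v)
  if (!is.null(samples))
    out$chain <- bps_chain(samples[, seq_len(samp_k - 1L), drop = FALSE],
                           d = d, N = N, delta = delta)
  class(out) <- "bps_trajectory"
  out
}

#' @export
print.bps_trajectory <- function(x, ...) {
  cat(sprintf("bps_trajectory (%s on '%s'): T = %g, %d events\n",
              x$sampler, x$model, x$horizon, nrow(x$events)))
  print(x$counters)
  invisible(x)
}

#' Tune the lookahead window
#'
#' Fixed-point iteration on short pilot runs so that the expected number of
#' events generated by the bounding process per window is approximately one:
#' `theta * mean(total bound rate) ~ 1`.
#'
#' @inheritParams simulate_blocked_bps
#' @param pilot_time length of each pilot run in sampler seconds.
#' @param iterations number of fixed-point refinements.
#' @return tuned `theta`; falls back to `config$theta` with a warning when a
#'   pilot generates no proposals (e.g. a constant potential).
#' @export
tune_theta <- function(model, strategy, config, pilot_time = 10, iterations = 4L) {
  if (pilot_time <= 0) stop("pilot_time must be positive")
  theta <- config$theta
  for (it in seq_len(iterations)) {
    cfg <- config
    cfg$theta <- theta
    cfg$horizon <- pilot_time
    cfg$delta <- NULL; cfg$store_skeleton <- FALSE
    run <- simulate_blocked_bps(model, strategy, cfg)
    n_prop <- run$counters[["proposals"]]
    if (n_prop == 0) {
      warning("pilot run generated no proposals; returning config theta")
      return(config$theta)
    }
    mean_rate <- n_prop / pilot_time    # realized bounding-process intensity
    theta <- 1 / mean_rate
  }
  theta
}

#' Thinned event times from a dominating Poisson process
#'
#' Reference implementation of the accept/reject step used by the samplers,
#' exposed for validating thinning correctness: propose from a homogeneous
#' process at the bound rate and accept with probability
#' `rate_fn(t) / bound`. With a constant true rate the inter-acceptance
#' times are exactly exponential with that rate.
#'
#' @param rate_fn vectorized function of time giving the true rate, must
#'   never exceed `bound`.
#' @param bound constant dominating rate.
#' @param horizon time horizon.
#' @return numeric vector of accepted event times.
#' @export
simulate_thinning <- function(rate_fn, bound, horizon) {
  times <- numeric(0)
  t <- 0
  repeat {
    t <- t + stats::rexp(1L) / bound
    if (t > horizon) break
    r <- rate_fn(t)
    if (r > bound) stop("true rate exceeds the bound at t = ", t)
    if (stats::runif(1L) * bound < r) times <- c(times, t)
  }
  times
}
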