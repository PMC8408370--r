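test_that("block rate is the clipped Frobenius inner product", {
  p <- lgssm_params(3, 20)
  y <- simulate_lgssm(p, 1)$y
  model <- lgssm_model(p, y)
  s <- make_temporal_strategy(3, 20, 8, 4)
  set.seed(2)
  for (r in 1:10) {
    x <- matrix(rnorm(60), 3, 20); v <- matrix(rnorm(60), 3, 20)
    b <- sample(nrow(s$blocks), 1)
    bb <- s$blocks[b, ]
    # naive double loop over the block entries
    g <- lgssm_grad(p, y, x)
    acc <- 0
    for (k in bb[1]:bb[2]) for (n in bb[3]:bb[4]) acc <- acc + g[k, n] * v[k, n]
    expect_equal(block_rate(model, s, x, v, b), max(0, acc), tolerance = 1e-12)
    # descent direction has rate zero
    v2 <- v
    v2[bb[1]:bb[2], bb[3]:bb[4]] <- -g[bb[1]:bb[2], bb[3]:bb[4]]
    expect_equal(block_rate(model, s, x, v2, b), 0)
  }
  # isotropic Gaussian with v_B = x_B: rate is the squared block norm
  mi <- iid_gaussian_model(3, 20)
  x <- matrix(rnorm(60), 3, 20)
  b <- 2L; bb <- s$blocks[b, ]
  expect_equal(block_rate(mi, s, x, x, b),
               sum(x[bb[1]:bb[2], bb[3]:bb[4]]^2), tolerance = 1e-12)
})

test_that("reflection is a norm-preserving involution acting only on the block", {
  p <- lgssm_params(3, 15)
  y <- simulate_lgssm(p, 2)$y
  model <- lgssm_model(p, y)
  s <- make_temporal_strategy(3, 15, 6, 3)
  set.seed(3)
  for (r in 1:50) {
    x <- matrix(rnorm(45), 3, 15); v <- matrix(rnorm(45), 3, 15)
    b <- sample(nrow(s$blocks), 1)
    bb <- s$blocks[b, ]
    rws <- bb[1]:bb[2]; cls <- bb[3]:bb[4]
    v1 <- reflect_block(model, s, x, v, b)
    # outside the block: untouched
    expect_identical(v1[, -cls], v[, -cls])
    # norm preservation and involution
    expect_lt(abs(sqrt(sum(v1[rws, cls]^2)) - sqrt(sum(v[rws, cls]^2))), 1e-10)
    expect_lt(max(abs(reflect_block(model, s, x, v1, b) - v)), 1e-10)
    # inner product with the block gradient flips sign
    g <- lgssm_grad(p, y, x)[rws, cls, drop = FALSE]
    expect_equal(sum(g * v1[rws, cls]), -sum(g * v[rws, cls]), tolerance = 1e-9)
  }
  # gradient-parallel velocity reverses; orthogonal velocity is unchanged
  mi <- iid_gaussian_model(2, 4)
  si <- make_temporal_strategy(2, 4, 4, 0)
  x <- matrix(c(1, 0, 0, 0, 0, 0, 0, 0), 2, 4)
  vpar <- 2 * x
  expect_equal(reflect_block(mi, si, x, vpar, 1), -vpar, tolerance = 1e-12)
  vorth <- matrix(c(0, 1, 0, 0, 0, 0, 0, 0), 2, 4)
  expect_equal(reflect_block(mi, si, x, vorth, 1), vorth, tolerance = 1e-12)
})

test_that("velocity refreshment is standard normal and reproducible", {
  set.seed(7)
  v <- refresh_velocity(matrix(0, 20, 50))
  expect_equal(dim(v), c(20, 50))
  expect_lt(abs(mean(v)), 3 / sqrt(1000))
  expect_lt(abs(var(as.vector(v)) - 1), 3 * sqrt(2 / 1000))
  set.seed(7)
  expect_identical(refresh_velocity(matrix(0, 20, 50)), v)
  # independence across components: neighbouring entries uncorrelated
  z <- as.vector(v)
  expect_lt(abs(cor(z[-1], z[-length(z)])), 0.1)
})

test_that("lookahead bounds dominate the rate over the whole window", {
  p <- lgssm_params(3, 30)
  y <- simulate_lgssm(p, 3)$y
  model <- lgssm_model(p, y)
  s <- make_temporal_strategy(3, 30, 10, 5)
  phi <- compute_phi(s)
  set.seed(8)
  x <- matrix(rnorm(90), 3, 30); v <- matrix(rnorm(90), 3, 30)
  theta <- 0.7
  for (b in c(1L, 3L)) {
    bd <- rate_bound_on_window(model, s, x, v, b, theta, phi = phi)
    # dense grid scan oracle (quadratic: endpoint max must dominate exactly)
    grid <- seq(0, theta, length.out = 10000)
    rates <- vapply(grid, function(ss)
      block_rate(model, s, x + ss * (phi * v), v, b), 0)
    expect_gte(bd$bound + 1e-10, max(rates))
    expect_lt(bd$bound - max(rates), 1e-6)
  }
  expect_equal(rate_bound_on_window(model, s, x, 0 * v, 1, theta, phi = phi)$bound, 0)

  # SV model: safety-inflated grid bound audited at random interior points
  ps <- sv_default_params(2, 12)
  sim <- simulate_sv(ps, 9)
  ms <- sv_model(ps, sim$data)
  ss <- make_temporal_strategy(2, 12, 6, 3)
  phis <- compute_phi(ss)
  xs <- matrix(rnorm(24) * 0.3, 2, 12); vs <- matrix(rnorm(24), 2, 12)
  bd <- rate_bound_on_window(ms, ss, xs, vs, 2, 0.2, phi = phis,
                             bound_grid = 16, bound_safety = 1.1)
  rr <- vapply(runif(1000, 0, 0.2), function(sp)
    block_rate(ms, ss, xs + sp * (phis * vs), vs, 2), 0)
  expect_true(all(rr <= bd$bound + 1e-10))
})

test_that("single-block sampler matches an independent reference implementation", {
  p <- lgssm_params(2, 8)
  y <- simulate_lgssm(p, 12)$y
  model <- lgssm_model(p, y)
  cfg <- sampler_config(horizon = 40, seed = 77, gamma_refresh = 0.3,
                        theta = 0.25, delta = 0.5)
  x0 <- matrix(0, 2, 8)
  set.seed(123); v0 <- matrix(rnorm(16), 2, 8)
  run <- simulate_global_bps(model, cfg, x0 = x0, v0 = v0)
  ref <- reference_single_block_bps(model, cfg, x0, v0)
  expect_equal(run$chain$samples, ref, tolerance = 1e-10)
})

test_that("sampler targets the correct distribution on exact closed forms", {
  # 1D standard normal through the full machinery
  m1 <- iid_gaussian_model(1, 1)
  cfg <- sampler_config(horizon = 10000, seed = 5, gamma_refresh = 0.5,
                        theta = 1, delta = 0.25)
  run <- simulate_blocked_bps(m1, make_temporal_strategy(1, 1, 1, 0), cfg)
  z <- run$chain$samples[1, -(1:4000)]
  ez <- ess(z)
  expect_lt(abs(mean(z)), 3 * sqrt(var(z) / ez))
  expect_lt(abs(var(z) - 1), 3 * sqrt(2 / ez) + 0.05)

  # 2D correlated Gaussian in the size-1-block (Zig-Zag-like) limit
  m2 <- gaussian_model_2d(0.6)
  szz <- blocking_strategy(rbind(c(1, 1, 1, 1), c(2, 2, 1, 1)), 2, 1)
  cfg2 <- sampler_config(horizon = 8000, seed = 2, gamma_refresh = 0.5,
                         theta = 0.3, delta = 0.25)
  rz <- simulate_blocked_bps(m2, szz, cfg2)
  s <- rz$chain$samples[, -(1:8000)]
  for (k in 1:2) {
    ek <- ess(s[k, ])
    expect_lt(abs(mean(s[k, ])), 4 * sqrt(var(s[k, ]) / ek))
    expect_lt(abs(var(s[k, ]) - 1), 4 * sqrt(2 / ek))
  }
  expect_lt(abs(cov(s[1, ], s[2, ]) - 0.6), 0.1)
})

test_that("trajectory skeleton is consistent with the block-augmented flow", {
  p <- lgssm_params(2, 20)
  y <- simulate_lgssm(p, 6)$y
  model <- lgssm_model(p, y)
  s <- make_temporal_strategy(2, 20, 8, 4)
  phi <- compute_phi(s)
  cfg <- sampler_config(horizon = 20, seed = 10, gamma_refresh = 0.2,
                        theta = 0.2, store_skeleton = TRUE)
  run <- simulate_blocked_bps(model, s, cfg)
  sk <- run$skeleton
  for (i in seq_len(length(sk$times) - 1L)) {
    dt <- sk$times[i + 1L] - sk$times[i]
    pred <- sk$x[[i]] + dt * (phi * sk$v[[i]])
    expect_lt(max(abs(pred - sk$x[[i + 1L]])), 1e-9)
  }
  # phi-speedup: between consecutive events, overlap coordinates (phi = 2)
  # traverse exactly twice the per-unit-velocity distance of phi = 1 ones
  i <- which(diff(sk$times) > 1e-4)[1]
  dt <- sk$times[i + 1L] - sk$times[i]
  disp <- (sk$x[[i + 1L]] - sk$x[[i]]) / (dt * sk$v[[i]])
  expect_equal(disp[phi == 2], rep(2, sum(phi == 2)), tolerance = 1e-8)
  expect_equal(disp[phi == 1], rep(1, sum(phi == 1)), tolerance = 1e-8)
})

test_that("bound audit catches a potential mislabelled as quadratic", {
  # U = cos(x): its rate along the flow peaks inside the lookahead window,
  # so the endpoint 'quadratic' bound is invalid and the audit must fail
  bad <- potential_model(1, 1, U = function(x) cos(x[1, 1]),
                         grad = function(x) -sin(x), quadratic = TRUE,
                         grad_dep_cols = 0L, name = "cosine")
  s <- make_temporal_strategy(1, 1, 1, 0)
  cfg <- sampler_config(horizon = 10, seed = 1, gamma_refresh = 0,
                        theta = pi - 0.2, audit = TRUE)
  expect_error(
    simulate_blocked_bps(bad, s, cfg, x0 = matrix(pi + 0.1, 1, 1),
                         v0 = matrix(1, 1, 1)),
    "audit failure")
})

test_that("thinning against a constant bound recovers the exponential law", {
  set.seed(42)
  times <- simulate_thinning(function(t) 2, bound = 4, horizon = 500)
  gaps <- diff(times)
  expect_equal(length(times) / 500, 2, tolerance = 0.1)
  expect_gt(ks.test(gaps, "pexp", 2)$p.value, 0.01)
  expect_error(simulate_thinning(function(t) 5, bound = 4, horizon = 10),
               "exceeds")
})

test_that("lookahead tuning equalizes events per window", {
  p <- lgssm_params(3, 30)
  y <- simulate_lgssm(p, 4)$y
  model <- lgssm_model(p, y)
  s <- make_temporal_strategy(3, 30, 10, 5)
  cfg <- sampler_config(horizon = 10, seed = 6, gamma_refresh = 0.1, theta = 1)
  th <- tune_theta(model, s, cfg, pilot_time = 20)
  # realized events per window near one
  cfg2 <- sampler_config(horizon = 50, seed = 7, gamma_refresh = 0.1, theta = th)
  run <- simulate_blocked_bps(model, s, cfg2)
  epw <- run$counters[["proposals"]] / 50 * th
  expect_gt(epw, 0.5); expect_lt(epw, 2)

  # doubling all rates roughly halves the tuned window (scale equivariance)
  y2 <- y * sqrt(2)
  doubled <- potential_model(3, 30, U = function(x) 2 * lgssm_potential(p, y, x),
                             grad = function(x) 2 * lgssm_grad(p, y, x),
                             block_grad = function(x, i, j, l, m)
                               2 * model$block_grad(x, i, j, l, m),
                             quadratic = TRUE, grad_dep_cols = 1L, name = "x2")
  # the fixed point couples theta to the window maximum, so the realized
  # ratio sits a little below the pure rate-time scaling of 2
  th2 <- tune_theta(doubled, s, cfg, pilot_time = 20)
  expect_gt(th / th2, 1.3); expect_lt(th / th2, 2.7)

  # constant potential: no events, warning path
  flat <- potential_model(2, 4, U = function(x) 0, grad = function(x) 0 * x,
                          quadratic = TRUE, grad_dep_cols = 0L, name = "flat")
  sflat <- make_temporal_strategy(2, 4, 4, 0)
  cfgf <- sampler_config(horizon = 5, seed = 2, gamma_refresh = 0, theta = 0.5)
  expect_warning(thf <- tune_theta(flat, sflat, cfgf, pilot_time = 2), "no proposals")
  expect_equal(thf, 0.5)
})
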