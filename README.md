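# blockbps

Event-driven, continuous-time MCMC for **smoothing in state-space models**:
given observations `y_{1:N}` of a latent process `x_{1:N}` with `x_n ∈ R^d`,
draw from the joint conditional `p(x_{1:N} | y_{1:N})`. The package is aimed
at statisticians and quantitative modellers who need full-trajectory
posteriors in settings where particle-based smoothers struggle — long time
series and/or non-trivial spatial dimension — and at methods researchers who
want a carefully validated reference implementation of blocked
piecewise-deterministic samplers.

## The algorithm

The sampler is a **blocked bouncy particle sampler**, a
piecewise-deterministic Markov process on state–velocity pairs
`(x, v) ∈ M_{d,N} × M_{d,N}`. Writing `U(x) = −log p(x_{1:N} | y_{1:N})` for
the potential, a *blocking strategy* covers the `d × N` index grid with
(possibly overlapping) rectangles; each block `B` carries a Poisson clock
with rate

    λ_B(x, v) = max{0, ⟨∇_B U(x), v_B⟩_F},

the positive part of the directional derivative of `U` restricted to the
block. At an event of block `B` only the submatrix `v_B` reflects in the
hyperplane orthogonal to the block gradient,

    v_B ← v_B − 2 ⟨∇_B U(x), v_B⟩_F / ‖∇_B U(x)‖²_F · ∇_B U(x),

and the state flows linearly as `x + t·(φ ⋆ v)`, where `φ` counts how many
blocks contain each coordinate — coordinates shared by `φ` blocks see events
`φ` times as often and move `φ` times as fast to compensate. Full velocity
refreshment at rate `γ` guarantees ergodicity. Event times are simulated by
Poisson thinning against per-block lookahead bounds (exact endpoint bounds
for Gaussian targets, safety-inflated grid bounds otherwise). A single
whole-grid block recovers the standard bouncy particle sampler; a
zero-overlap temporal cover gives the local/factor variant.

The **even–odd (partitioned) sampler** splits the strategy into sub-sets of
pairwise-disjoint blocks, runs one clock per sub-set at a bound on its
*maximum* block rate, and at an event updates **all** blocks of the ringing
sub-set simultaneously — each reflecting independently with probability
`λ_B/Λ̄`. The number of clocks is O(1) in the dimension, and the per-block
updates are order-independent by construction (bit-identical under permuted
processing, the contract that makes them parallelizable).

Two models ship with the package:

* a linear-Gaussian AR(1) model with kernel autoregressive matrix
  `A_ij = kern(i,j)/(ψ + Σ_l kern(i,l))`, `kern(i,j) = exp{−|i−j|²/(2σ²)}`,
  plus an exact Kalman/RTS smoother and exact joint posterior draws as
  oracles;
* a heavy-tailed stochastic volatility model with leverage:
  `x_{n+1} = A x_n + η_n`, `y_n = γ_n^{−1/2} Λ_n ε_n` with
  `Λ_n = diag(exp(x_n/2))`, jointly Gaussian `(η_n, ε_n)` with
  cross-covariance `Σ_ρ`, and `γ_n ~ Γ(ν/2, ν/2)` mixing (multivariate-t
  returns); inference conditions on the mixing variables through
  `y_n^γ = √γ_n · y_n`.

## Worked example

Smooth a simulated AR(1) model with an overlapping temporal strategy and
compare against the exact Kalman/RTS answer:

```r
library(blockbps)
params   <- lgssm_params(d = 3, N = 50, sigma2 = 5, psi = 0.1)
sim      <- simulate_lgssm(params, seed = 42)
model    <- lgssm_model(params, sim$y)

strategy <- make_temporal_strategy(d = 3, N = 50, width = 20, overlap = 10)
strategy
#> blocking_strategy: 4 blocks on a 3 x 50 grid
#> phi histogram: 1:60 2:90

config <- sampler_config(horizon = 1000, seed = 7, gamma_refresh = 0.1,
                         theta = 0.05, delta = 0.1)
run <- simulate_blocked_bps(model, strategy, config)
run
#> bps_trajectory (blocked_bps on 'lgssm'): T = 1000, 55044 events
#>            proposals          acceptances           rejections
#>                34482                18419                16063
#>            refreshes             expiries bound_recomputations
#>                   78                20484               114563

oracle <- kalman_rts_smoother(params, sim$y)
est <- matrix(rowMeans(run$chain$samples[, -(1:2500)]), 3, 50)
sqrt(mean((est - oracle$means)^2))
#> [1] 0.007027786

ess(chain_coord(run$chain, k = 1, n = 25))
#> [1] 1330.776
mean_square_jump_distance(run$chain, k = 1, n = 25)
#> [1] 0.03490783
```

The 150 coordinates were covered by 4 width-20 blocks with overlap 10; 90 of
them sit in two blocks (`φ = 2`) and travel at doubled speed. After
discarding 25% burn-in, the posterior-mean estimate from 1000 sampler
seconds is within 0.007 root-mean-square of the exact smoothing means, with
an effective sample size of about 1300 for the middle coordinate. The
even–odd variant runs the same way via `even_odd_partition()` and
`simulate_even_odd_bps()`; `simulate_global_bps()` and
`simulate_local_bps()` give the single-block and factor baselines.

A command-line interface (`inst/cli/blockbps`) exposes
`simulate` / `sample` / `diagnose` subcommands over YAML or JSON configs.

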