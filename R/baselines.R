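# Reference samplers: the standard (single-block, "global") bouncy particle
# sampler and the factor/"local" variant over a non-overlapping temporal
# cover. Both are exact special cases of the blocked sampler (phi = 1
# everywhere), which keeps the comparison surface identical.

#' Standard bouncy particle sampler
#'
#' The blocked sampler with the trivial strategy of a single block covering
#' the whole grid: one reflection clock, whole-matrix reflections,
#' `phi = 1` everywhere.
#'
#' @inheritParams simulate_blocked_bps
#' @return a `bps_trajectory`.
#' @export
simulate_global_bps <- function(model, config, x0 = NULL, v0 = NULL) {
  strat <- make_temporal_strategy(model$d, model$N, width = model$N, overlap = 0L)
  out <- simulate_blocked_bps(model, strat, config, x0 = x0, v0 = v0)
  out$sampler <- "global_bps"
  out
}

#' Local (factor) bouncy particle sampler
#'
#' The blocked sampler over a non-overlapping temporal strategy of the given
#' width: block-restricted gradients of the full potential, `phi = 1`
#' everywhere, event rate equal to the sum over factors.
#'
#' @inheritParams simulate_blocked_bps
#' @param width temporal width of each factor.
#' @return a `bps_trajectory`.
#' @export
simulate_local_bps <- function(model, width, config, x0 = NULL, v0 = NULL) {
  strat <- make_temporal_strategy(model$d, model$N, width = width, overlap = 0L)
  out <- simulate_blocked_bps(model, strat, config, x0 = x0, v0 = v0)
  out$sampler <- "local_bps"
  out
}
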