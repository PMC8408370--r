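# Potential-model interface: a differentiable state-space model is exposed to
# the samplers as its potential U(x) = -log p(x_{1:N} | y_{1:N}) (all
# normalization constants included), the gradient map d x N -> d x N, and a
# block-restricted gradient used by the event-rate computations.

#' Construct a potential model
#'
#' Wraps a potential `U`, its gradient, and (optionally) a block-restricted
#' gradient into the interface consumed by the samplers. States are `d x N`
#' matrices: rows are spatial dimensions, columns time points.
#'
#' @param d,N spatial dimension and number of time points.
#' @param U function of a `d x N` matrix returning a scalar: the negative log
#'   joint density of the latent states given the observations.
#' @param grad function returning the `d x N` gradient matrix of `U`.
#' @param block_grad optional `function(x, i, j, l, m)` returning
#'   `grad(x)[i:j, l:m]` without forming the full gradient; defaults to
#'   subsetting `grad(x)`.
#' @param quadratic logical; `TRUE` when `U` is a quadratic form (Gaussian
#'   target), in which case directional derivatives are affine along the flow
#'   and lookahead rate bounds are exact endpoint maxima.
#' @param grad_dep_cols how many time columns beyond a block's own range its
#'   block gradient depends on: 1 for first-order Markov models, `Inf`
#'   (default) for unknown/global dependence. Controls which lookahead
#'   bounds are invalidated by a reflection.
#' @param name model label used in logs and manifests.
#' @return an object of class `potential_model`.
#' @export
potential_model <- function(d, N, U, grad, block_grad = NULL,
                            quadratic = FALSE, grad_dep_cols = Inf,
                            name = "custom") {
  if (is.null(block_grad))
    block_grad <- function(x, i, j, l, m) grad(x)[i:j, l:m, drop = FALSE]
  structure(list(d = as.integer(d), N = as.integer(N), U = U, grad = grad,
                 block_grad = block_grad, quadratic = isTRUE(quadratic),
                 grad_dep_cols = grad_dep_cols, name = name),
            class = "potential_model")
}

#' @export
print.potential_model <- function(x, ...) {
  cat(sprintf("potential_model '%s': d = %d, N = %d (%s potential)\n",
              x$name, x$d, x$N, if (x$quadratic) "quadratic" else "general"))
  invisible(x)
}

check_state <- function(model, x, what = "state") {
  if (!is.matrix(x) || nrow(x) != model$d || ncol(x) != model$N)
    stop(what, " must be a ", model$d, " x ", model$N, " matrix")
  if (!all(is.finite(x))) stop(what, " contains non-finite entries")
  invisible(x)
}
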