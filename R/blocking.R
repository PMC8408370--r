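# Blocking strategies: rectangular covers of the d x N state-index grid.
# A block is i:j x l:m (1-based, inclusive); i indexes space (rows), l time
# (columns). Stored as an nb x 4 integer matrix with columns i, j, l, m.

#' Construct a blocking strategy from explicit blocks
#'
#' A blocking strategy is a cover of the index grid `[d] x [N]` by axis-aligned
#' rectangles ("blocks"). Blocks may overlap; coordinates shared by several
#' blocks are flowed proportionally faster by the sampler (see
#' [compute_phi()]).
#'
#' @param blocks integer matrix with one row per block and columns
#'   `i, j, l, m`: the block covers spatial rows `i:j` and time columns `l:m`.
#' @param d,N grid dimensions (spatial, temporal).
#' @param meta optional list of builder metadata (widths, overlaps, axis
#'   start grids) attached verbatim.
#' @return an object of class `blocking_strategy`.
#' @export
blocking_strategy <- function(blocks, d, N, meta = list()) {
  blocks <- matrix(as.integer(blocks), ncol = 4L,
                   dimnames = list(NULL, c("i", "j", "l", "m")))
  if (nrow(blocks) == 0L) stop("a blocking strategy needs at least one block")
  if (any(blocks[, "i"] < 1L) || any(blocks[, "j"] > d) ||
      any(blocks[, "l"] < 1L) || any(blocks[, "m"] > N) ||
      any(blocks[, "i"] > blocks[, "j"]) || any(blocks[, "l"] > blocks[, "m"]))
    stop("invalid block ranges for a ", d, " x ", N, " grid")
  s <- structure(list(blocks = blocks, d = as.integer(d), N = as.integer(N),
                      meta = meta),
                 class = "blocking_strategy")
  phi <- compute_phi(s)
  if (any(phi < 1L)) stop("blocks do not cover the ", d, " x ", N, " grid")
  s
}

#' @export
print.blocking_strategy <- function(x, ...) {
  cat(sprintf("blocking_strategy: %d blocks on a %d x %d grid\n",
              nrow(x$blocks), x$d, x$N))
  phi <- compute_phi(x)
  tab <- table(phi)
  cat("phi histogram:", paste(sprintf("%s:%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

# Per-axis start positions: stride = width - overlap, plus an end-anchored
# final block so the cover reaches the boundary exactly.
axis_starts <- function(extent, width, overlap) {
  if (width > extent) stop("block width ", width, " exceeds axis extent ", extent)
  if (overlap < 0L || overlap >= width) stop("need 0 <= overlap < width")
  stride <- width - overlap
  starts <- seq.int(1L, extent - width + 1L, by = stride)
  if (starts[length(starts)] + width - 1L < extent)
    starts <- c(starts, extent - width + 1L)
  as.integer(starts)
}

#' Temporal blocking strategy
#'
#' Blocks of the form `1:d x l:m` with fixed temporal width, advancing by
#' `width - overlap`; the final block is end-anchored so that the cover ends
#' exactly at column `N`.
#'
#' @param d,N grid dimensions.
#' @param width temporal block width.
#' @param overlap temporal overlap between consecutive blocks
#'   (`0 <= overlap < width`).
#' @return a [blocking_strategy()].
#' @examples
#' s <- make_temporal_strategy(3, 100, width = 20, overlap = 10)
#' nrow(s$blocks)
#' @export
make_temporal_strategy <- function(d, N, width, overlap = 0L) {
  st <- axis_starts(N, width, overlap)
  blocks <- cbind(i = 1L, j = as.integer(d), l = st, m = st + as.integer(width) - 1L)
  blocking_strategy(blocks, d, N,
                    meta = list(kind = "temporal", t_width = width,
                                t_overlap = overlap, t_starts = st,
                                s_starts = 1L, grid = cbind(si = rep(1L, length(st)),
                                                            ti = seq_along(st))))
}

#' Spatiotemporal blocking strategy
#'
#' Cartesian product of per-axis start grids: spatial blocks of height
#' `s_width` and temporal blocks of width `t_width`, each axis end-anchored.
#' Block order is row-major: spatial position outer, temporal inner.
#'
#' @param d,N grid dimensions.
#' @param s_width,t_width block height (spatial) and width (temporal).
#' @param s_overlap,t_overlap per-axis overlaps.
#' @return a [blocking_strategy()].
#' @export
make_spatiotemporal_strategy <- function(d, N, s_width, t_width,
                                         s_overlap = 0L, t_overlap = 0L) {
  ss <- axis_starts(d, s_width, s_overlap)
  ts <- axis_starts(N, t_width, t_overlap)
  grid <- expand.grid(ti = seq_along(ts), si = seq_along(ss))[, c("si", "ti")]
  blocks <- cbind(i = ss[grid$si], j = ss[grid$si] + as.integer(s_width) - 1L,
                  l = ts[grid$ti], m = ts[grid$ti] + as.integer(t_width) - 1L)
  blocking_strategy(blocks, d, N,
                    meta = list(kind = "spatiotemporal",
                                s_width = s_width, t_width = t_width,
                                s_overlap = s_overlap, t_overlap = t_overlap,
                                s_starts = ss, t_starts = ts,
                                grid = as.matrix(grid)))
}

#' Block-membership counts
#'
#' `phi[k, n]` counts how many blocks contain coordinate `(k, n)`. Under the
#' blocked sampler the state flows as `x + t * (phi * v)`: coordinates shared
#' by `k` blocks see events `k` times as often, so they move `k` times as
#' fast to compensate.
#'
#' @param strategy a [blocking_strategy()].
#' @return a `d x N` integer matrix, every entry `>= 1`.
#' @export
compute_phi <- function(strategy) {
  phi <- matrix(0L, strategy$d, strategy$N)
  b <- strategy$blocks
  for (r in seq_len(nrow(b)))
    phi[b[r, 1L]:b[r, 2L], b[r, 3L]:b[r, 4L]] <-
      phi[b[r, 1L]:b[r, 2L], b[r, 3L]:b[r, 4L]] + 1L
  phi
}

blocks_intersect <- function(b1, b2) {
  b1[1L] <= b2[2L] && b2[1L] <= b1[2L] && b1[3L] <= b2[4L] && b2[3L] <= b1[4L]
}

#' Neighborhood of a block
#'
#' All blocks whose rectangle intersects the given block's, including the
#' block itself. After a reflection in block `B` only the rate bounds of
#' `N(B)` need recomputation.
#'
#' @param strategy a [blocking_strategy()].
#' @param block_index index into the strategy's block list.
#' @return sorted integer vector of block indices, always containing
#'   `block_index`.
#' @export
neighbors <- function(strategy, block_index) {
  b <- strategy$blocks
  if (block_index < 1L || block_index > nrow(b)) stop("block index out of range")
  q <- b[block_index, ]
  hit <- b[, "i"] <= q["j"] & q["i"] <= b[, "j"] &
         b[, "l"] <= q["m"] & q["l"] <= b[, "m"]
  which(hit)
}

neighbor_list <- function(strategy) {
  lapply(seq_len(nrow(strategy$blocks)), function(b) neighbors(strategy, b))
}

#' Partition of a blocking strategy into disjoint sub-strategies
#'
#' @param groups list of integer vectors of block indices; the vectors must
#'   partition `1:nb`.
#' @param labels optional character labels (e.g. `"odd"`, `"even"`).
#' @return object of class `block_partition`.
#' @export
block_partition <- function(groups, labels = NULL) {
  if (is.null(labels)) labels <- as.character(seq_along(groups))
  structure(list(groups = lapply(groups, as.integer), labels = labels),
            class = "block_partition")
}

#' Validate a partition against the disjointness assumption
#'
#' Checks that the sub-strategies partition the block list and that blocks
#' within each sub-strategy are pairwise disjoint (so all blocks of a
#' sub-strategy can update their velocities simultaneously).
#'
#' @param strategy a [blocking_strategy()].
#' @param partition a [block_partition()].
#' @return list with `valid` (logical) and `violations` (data.frame with
#'   columns `group, block1, block2, reason`).
#' @export
validate_partition <- function(strategy, partition) {
  nb <- nrow(strategy$blocks)
  viol <- list()
  idx <- sort(unlist(partition$groups))
  if (!identical(idx, seq_len(nb)))
    viol[[length(viol) + 1L]] <- data.frame(group = NA_integer_, block1 = NA_integer_,
                                            block2 = NA_integer_,
                                            reason = "groups do not partition the block list")
  for (g in seq_along(partition$groups)) {
    ids <- partition$groups[[g]]
    if (length(ids) < 2L) next
    for (a in seq_len(length(ids) - 1L)) for (b in (a + 1L):length(ids)) {
      if (blocks_intersect(strategy$blocks[ids[a], ], strategy$blocks[ids[b], ]))
        viol[[length(viol) + 1L]] <- data.frame(group = g, block1 = ids[a],
                                                block2 = ids[b],
                                                reason = "overlapping blocks in one sub-strategy")
    }
  }
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(group = integer(), block1 = integer(), block2 = integer(),
               reason = character())
  list(valid = nrow(violations) == 0L, violations = violations)
}

#' Even-odd partition of a temporal strategy
#'
#' Splits a temporal chain of blocks into two sub-strategies by alternating
#' block order; valid whenever each block intersects only its immediate
#' neighbours in the chain (overlap smaller than the stride to the
#' next-but-one block).
#'
#' @param strategy a temporal [blocking_strategy()].
#' @return a [block_partition()] with labels `odd`, `even`.
#' @export
even_odd_partition <- function(strategy) {
  nb <- nrow(strategy$blocks)
  odd <- seq(1L, nb, by = 2L)
  even <- if (nb > 1L) seq(2L, nb, by = 2L) else integer()
  groups <- if (length(even)) list(odd, even) else list(odd)
  p <- block_partition(groups, labels = c("odd", "even")[seq_along(groups)])
  chk <- validate_partition(strategy, p)
  if (!chk$valid)
    stop("even-odd partition infeasible: blocks ",
         chk$violations$block1[1L], " and ", chk$violations$block2[1L],
         " in the same sub-strategy intersect")
  p
}

#' Four-clock partition of a spatiotemporal grid strategy
#'
#' Checkerboard colouring by (spatial parity, temporal parity) of the block's
#' position in the builder's start grid; valid when each block intersects
#' only its (at most 8) grid neighbours.
#'
#' @param strategy a grid-structured [blocking_strategy()] produced by
#'   [make_spatiotemporal_strategy()] (or [make_temporal_strategy()]).
#' @return a [block_partition()] with up to four groups.
#' @export
four_clock_partition <- function(strategy) {
  grid <- strategy$meta$grid
  if (is.null(grid)) stop("four_clock_partition needs a grid-structured strategy")
  colour <- 2L * (grid[, "si"] %% 2L) + (grid[, "ti"] %% 2L) + 1L
  keep <- sort(unique(colour))
  groups <- lapply(keep, function(cc) which(colour == cc))
  p <- block_partition(groups, labels = paste0("clock", seq_along(groups)))
  chk <- validate_partition(strategy, p)
  if (!chk$valid)
    stop("four-clock partition infeasible: blocks ",
         chk$violations$block1[1L], " and ", chk$violations$block2[1L],
         " in the same sub-strategy intersect")
  p
}

# Exact chromatic number by iterative-deepening backtracking on the
# intersection graph; vertices in decreasing-degree order.
chromatic_exact <- function(adj) {
  n <- nrow(adj)
  ord <- order(rowSums(adj), decreasing = TRUE)
  for (k in 1:n) {
    colours <- integer(n)
    assign_next <- function(pos) {
      if (pos > n) return(TRUE)
      v <- ord[pos]
      used <- unique(colours[which(adj[v, ] & colours > 0L)])
      for (cc in setdiff(seq_len(min(k, pos)), used)) {
        colours[v] <<- cc
        if (assign_next(pos + 1L)) return(TRUE)
        colours[v] <<- 0L
      }
      FALSE
    }
    if (assign_next(1L)) return(k)
  }
  n
}

#' Smallest feasible number of disjoint sub-strategies
#'
#' The minimum `K` for which the strategy admits a partition into `K`
#' internally disjoint sub-strategies, i.e. the chromatic number of the
#' block-intersection graph. Computed exactly for up to 20 blocks
#' (backtracking), otherwise bounded from above by a greedy colouring.
#'
#' @param strategy a [blocking_strategy()].
#' @return integer `K` with attribute `method` (`"exact"` or `"greedy"`).
#' @export
min_partition_size <- function(strategy) {
  b <- strategy$blocks
  nb <- nrow(b)
  adj <- matrix(FALSE, nb, nb)
  for (a in seq_len(nb)) {
    hit <- b[, "i"] <= b[a, "j"] & b[a, "i"] <= b[, "j"] &
           b[, "l"] <= b[a, "m"] & b[a, "l"] <= b[, "m"]
    adj[a, ] <- hit
  }
  diag(adj) <- FALSE
  if (nb <= 20L) {
    k <- chromatic_exact(adj)
    method <- "exact"
  } else {
    # greedy in block order: row-major construction order is a perfect
    # elimination ordering for temporal (interval-graph) strategies, where
    # this attains the chromatic number; otherwise it is an upper bound
    colours <- integer(nb)
    for (v in seq_len(nb)) {
      used <- colours[which(adj[v, ] & colours > 0L)]
      colours[v] <- min(setdiff(seq_len(nb), used))
    }
    k <- max(colours)
    method <- "greedy"
  }
  structure(as.integer(k), method = method)
}

#' Serialize a strategy and optional partition to JSON
#'
#' @param strategy a [blocking_strategy()].
#' @param partition optional [block_partition()].
#' @param path file path; if `NULL` the JSON string is returned.
#' @return invisibly, the JSON string.
#' @export
strategy_to_json <- function(strategy, partition = NULL, path = NULL) {
  obj <- list(d = strategy$d, N = strategy$N,
              blocks = unname(apply(strategy$blocks, 1L, as.list)))
  if (!is.null(partition))
    obj$partition <- stats::setNames(partition$groups, partition$labels)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE)
  if (!is.null(path)) writeLines(js, path)
  invisible(js)
}
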