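test_that("temporal builder reproduces stride arithmetic and end-anchoring", {
  s <- make_temporal_strategy(3, 1000, width = 20, overlap = 0)
  expect_equal(nrow(s$blocks), 50L)
  expect_true(all(s$blocks[, "m"] - s$blocks[, "l"] + 1L == 20L))

  s1 <- make_temporal_strategy(3, 20, width = 20, overlap = 10)
  expect_equal(nrow(s1$blocks), 1L)

  s2 <- make_temporal_strategy(3, 100, width = 20, overlap = 10)
  expect_equal(s2$blocks[, "l"], seq(1L, 81L, by = 10L))

  # end-anchoring: non-dividing extent gets a final block ending exactly at N
  s3 <- make_temporal_strategy(2, 25, width = 20, overlap = 10)
  expect_equal(unname(s3$blocks[nrow(s3$blocks), "m"]), 25L)
  expect_true(all(diff(s3$blocks[, "l"]) > 0))
  expect_false(any(duplicated(s3$blocks)))

  expect_error(make_temporal_strategy(3, 100, width = 10, overlap = 10), "overlap")
  expect_error(make_temporal_strategy(3, 10, width = 20), "exceeds")
})

test_that("spatiotemporal builder covers the grid and reduces to temporal", {
  s <- make_spatiotemporal_strategy(3, 100, s_width = 3, t_width = 20,
                                    s_overlap = 0, t_overlap = 10)
  st <- make_temporal_strategy(3, 100, width = 20, overlap = 10)
  expect_equal(unname(s$blocks), unname(st$blocks))

  g <- make_spatiotemporal_strategy(4, 6, 2, 2, 1, 1)
  # exhaustive membership check of the cover property
  expect_true(all(brute_phi(g) >= 1L))
  expect_true(all(g$blocks[, "j"] - g$blocks[, "i"] + 1L <= 2L))
  expect_true(all(g$blocks[, "m"] - g$blocks[, "l"] + 1L <= 2L))
})

test_that("phi matches brute-force membership counting", {
  strategies <- list(
    make_temporal_strategy(3, 60, 20, 10),
    make_temporal_strategy(1, 30, 7, 3),
    make_spatiotemporal_strategy(5, 24, 3, 9, 1, 4),
    blocking_strategy(rbind(c(1, 3, 1, 30)), 3, 30))
  for (s in strategies)
    expect_identical(compute_phi(s), brute_phi(s))
  # stated overlap pattern: two temporal blocks sharing columns 11..20
  s2 <- blocking_strategy(rbind(c(1, 2, 1, 20), c(1, 2, 11, 30)), 2, 30)
  phi <- compute_phi(s2)
  expect_true(all(phi[, 11:20] == 2L) && all(phi[, c(1:10, 21:30)] == 1L))
  # the fast path on the larger width-20/overlap-10 chain
  big <- make_temporal_strategy(3, 1000, 20, 10)
  expect_identical(compute_phi(big), brute_phi(big))
})

test_that("neighborhoods are exact rectangle intersections and symmetric", {
  s0 <- make_temporal_strategy(2, 100, 20, 0)
  for (b in seq_len(nrow(s0$blocks)))
    expect_identical(neighbors(s0, b), b)

  s <- make_temporal_strategy(2, 100, 20, 10)
  interior <- 4L
  expect_identical(neighbors(s, interior), c(3L, 4L, 5L))
  for (b in seq_len(nrow(s$blocks)))
    for (bb in neighbors(s, b))
      expect_true(b %in% neighbors(s, bb))
  expect_error(neighbors(s, 99L), "out of range")
})

test_that("even-odd partition alternates and respects disjointness", {
  s <- make_temporal_strategy(3, 1000, 20, 10)
  p <- even_odd_partition(s)
  expect_length(p$groups, 2L)
  expect_true(validate_partition(s, p)$valid)
  expect_true(brute_validate(s, p))

  # non-overlapping strategy: trivially valid
  expect_true(validate_partition(
    s0 <- make_temporal_strategy(3, 100, 20, 0), even_odd_partition(s0))$valid)

  # three pairwise-intersecting blocks make alternation infeasible
  bad <- blocking_strategy(rbind(c(1, 2, 1, 30), c(1, 2, 20, 50), c(1, 2, 25, 60)),
                           2, 60)
  expect_error(even_odd_partition(bad), "infeasible")
})

test_that("four-clock partition colours a doubly-overlapping grid", {
  # grid chosen so both axes tile exactly (stride divides extent - width);
  # end-anchored extra blocks can force a same-parity intersection, see below
  s <- make_spatiotemporal_strategy(27, 754, s_width = 7, t_width = 9,
                                    s_overlap = 3, t_overlap = 4)
  p <- four_clock_partition(s)
  expect_length(p$groups, 4L)
  chk <- validate_partition(s, p)
  expect_true(chk$valid)
  expect_true(brute_validate(s, p))

  # diagonal grid neighbours (intersecting on both axes) get distinct colours
  grid <- s$meta$grid
  colour_of <- integer(nrow(s$blocks))
  for (g in seq_along(p$groups)) colour_of[p$groups[[g]]] <- g
  a <- which(grid[, "si"] == 1L & grid[, "ti"] == 1L)
  diagb <- which(grid[, "si"] == 2L & grid[, "ti"] == 2L)
  expect_true(diagb %in% neighbors(s, a))
  expect_true(colour_of[a] != colour_of[diagb])

  # no spatial overlap: four colours remain valid
  s2 <- make_spatiotemporal_strategy(6, 40, 3, 10, 0, 5)
  expect_true(validate_partition(s2, four_clock_partition(s2))$valid)

  # when an end-anchored extra block intersects a same-parity block the
  # checkerboard is infeasible and must say so rather than mis-colour
  s3 <- make_spatiotemporal_strategy(29, 754, 7, 9, 3, 4)
  expect_error(four_clock_partition(s3), "infeasible")
})

test_that("validate_partition agrees with the brute-force pairwise oracle", {
  s <- make_temporal_strategy(2, 80, 20, 10)
  one <- block_partition(list(seq_len(nrow(s$blocks))))
  chk <- validate_partition(s, one)
  expect_false(chk$valid)
  expect_true(nrow(chk$violations) > 0)

  set.seed(31)
  for (rep in 1:20) {
    k <- sample(2:4, 1)
    groups <- split(seq_len(nrow(s$blocks)),
                    sample(seq_len(k), nrow(s$blocks), replace = TRUE))
    groups <- Filter(length, groups)
    p <- block_partition(unname(groups))
    expect_identical(validate_partition(s, p)$valid, brute_validate(s, p))
  }
})

test_that("minimal partition size is the intersection-graph chromatic number", {
  expect_identical(as.integer(min_partition_size(make_temporal_strategy(3, 100, 20, 0))), 1L)

  s2 <- make_temporal_strategy(3, 200, 20, 10)   # 19 blocks: exact colouring
  k2 <- min_partition_size(s2)
  expect_identical(as.integer(k2), 2L)
  expect_identical(attr(k2, "method"), "exact")

  # doubly-overlapping grid needs the four-clock system
  s4 <- make_spatiotemporal_strategy(10, 24, 7, 9, 3, 4)
  k4 <- min_partition_size(s4)
  expect_identical(as.integer(k4), 4L)
  expect_identical(attr(k4, "method"), "exact")

  # greedy path on a long chain still finds the optimum (interval order)
  big <- make_temporal_strategy(3, 1000, 20, 10)
  kb <- min_partition_size(big)
  expect_identical(as.integer(kb), 2L)
  expect_identical(attr(kb, "method"), "greedy")
})

test_that("strategies serialize to JSON with their partition", {
  s <- make_temporal_strategy(2, 40, 20, 10)
  js <- strategy_to_json(s, even_odd_partition(s))
  parsed <- jsonlite::fromJSON(js, simplifyDataFrame = FALSE)
  expect_equal(parsed$d, 2)
  expect_equal(length(parsed$blocks), nrow(s$blocks))
  expect_named(parsed$partition, c("odd", "even"))
})
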