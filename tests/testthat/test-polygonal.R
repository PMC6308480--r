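test_that("curvature is zero on straight lines and peaks at a triangle apex", {
  y <- 0.5 * (0:20) + 3           # straight line, any slope
  cv <- curvature(y, support_k = 2)
  expect_true(all(cv < 1e-9))

  tri <- c(rep(0, 8), 1, 2, 3, 2, 1, rep(0, 8))  # symmetric triangular peak
  cv <- curvature(tri, support_k = 2)
  expect_equal(which.max(cv), 11)
})

test_that("curvature matches the direct per-sample angle oracle", {
  set.seed(11)
  y <- random_segment(15, seed = 11)
  for (k in c(1, 2, 3)) {
    expect_equal(curvature(y, k), oracle_curvature(y, k), tolerance = 1e-12)
  }
})

test_that("initial vertices are endpoints plus thresholded curvature maxima", {
  y <- seq(0, 5, length.out = 30)
  iv <- initial_vertices(y, support_k = 2, curv_threshold = 0.15)
  expect_equal(iv$vx, c(1L, 30L))

  pulse <- c(rep(0, 10), 1, 2, 3, 2, 1, rep(0, 10))
  iv <- initial_vertices(pulse, support_k = 1, curv_threshold = 0.15)
  # endpoints + apex + two baseline corners
  expect_equal(iv$vx, c(1L, 10L, 13L, 16L, 25L))
  expect_true(all(iv$vy == pulse[iv$vx]))

  iv <- initial_vertices(pulse, support_k = 1, curv_threshold = pi)
  expect_equal(iv$vx, c(1L, 25L))
})

test_that("sequential approximation meets its deviation bound", {
  y <- seq(2, 9, length.out = 25)
  vs <- sequential_approximation(y, 1, 25, tolerance = 0.02)
  expect_equal(vs$vx, c(1L, 25L))   # linear signal needs no additions

  spike <- rep(0, 21); spike[11] <- 1   # normalized spike deviation = 1
  vs <- sequential_approximation(spike, 1, 21, tolerance = 0.5)
  expect_equal(vs$vx, c(1L, 11L, 21L))  # one split at the spike suffices

  for (seed in 1:20) {
    y <- random_segment(40, seed)
    tol <- 0.05
    vs <- sequential_approximation(y, 1, 40, tolerance = tol)
    expect_lte(max(oracle_deviation(y, vs$vx)), tol + 1e-12)
  }
  expect_error(sequential_approximation(y, 10, 10, 0.1), "exceed")
})

test_that("dp_optimize recovers exact breakpoints and matches enumeration", {
  v <- vertex_set(c(1L, 30L), c(0, 0))
  y <- rep(0, 30)
  expect_identical(dp_optimize(y, v), v)      # m = 0 is the identity

  # piecewise-linear signal, one true breakpoint at 13, knot misplaced at 5
  y <- c(seq(0, 6, length.out = 13), seq(6, 2, length.out = 19)[-1])
  v0 <- vertex_set(c(1L, 5L, 31L), y[c(1, 5, 31)])
  opt <- dp_optimize(y, v0)
  expect_equal(opt$vx, c(1L, 13L, 31L))
  expect_lt(oracle_sse(y, opt$vx), 1e-18)

  for (seed in 1:10) {
    y <- random_segment(25, seed + 100)
    v0 <- vertex_set(c(1L, 8L, 9L, 25L), y[c(1, 8, 9, 25)])
    opt <- dp_optimize(y, v0)
    expect_equal(oracle_sse(y, opt$vx), oracle_dp_optimum(y, 1, 25, 2),
                 tolerance = 1e-9)
    expect_lte(oracle_sse(y, opt$vx), oracle_sse(y, v0$vx) + 1e-12)
  }
})

test_that("approximate composes the stages and preserves fiducial vertices", {
  y <- seq(-1, 1, length.out = 50)
  vs <- approximate(y, support_k = 5)
  expect_equal(vs$vx, c(1L, 50L))

  sim <- generate_record(beat_spec(), n_beats = 4, rr_s = 0.8, fs = 250)
  segs <- segment_rr(sim$record, sim$r_positions)
  qon <- ann_indices(sim$truth, "Qon")
  soff <- ann_indices(sim$truth, "Soff")
  for (i in seq_along(segs)) {
    seg <- segs[[i]]
    vs <- approximate(seg)
    expect_equal(vs$vx[1], 1L)
    expect_equal(vs$vx[nrow(vs)], length(seg$samples))
    expect_true(all(vs$vy == seg$samples[vs$vx]))
    qon_loc <- qon[i + 1] - seg$start_index + 1
    soff_loc <- soff[i] - seg$start_index + 1
    expect_lte(min(abs(vs$vx - qon_loc)), 1)
    expect_lte(min(abs(vs$vx - soff_loc)), 1)
  }
})

test_that("vertex count is non-increasing in tolerance", {
  sim <- generate_record(beat_spec(), n_beats = 3, rr_s = 0.8, fs = 250,
                         noise = test_noise(5))
  seg <- segment_rr(sim$record, sim$r_positions)[[1]]
  counts <- vapply(c(0.01, 0.02, 0.05, 0.1), function(tol) {
    nrow(approximate(seg, tolerance = tol))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("approximate vertex positions are invariant under polarity flip", {
  sim <- generate_record(beat_spec(), n_beats = 3, rr_s = 0.8, fs = 250,
                         noise = test_noise(9))
  seg <- segment_rr(sim$record, sim$r_positions)[[1]]
  v1 <- approximate(seg)
  v2 <- approximate(-seg$samples, support_k = 5)
  expect_identical(v1$vx, v2$vx)
  expect_equal(v2$vy, -v1$vy)
})

test_that("reconstruct interpolates linearly and is exact at vertices", {
  v <- vertex_set(c(1L, 5L), c(0, 4))
  expect_equal(reconstruct(v, 5), c(0, 1, 2, 3, 4))
  set.seed(2)
  y <- random_segment(60, 2)
  vs <- approximate(y, support_k = 3, tolerance = 0.02)
  rec <- reconstruct(vs, 60)
  expect_equal(rec[vs$vx], vs$vy)
  expect_lte(max(oracle_deviation(y, vs$vx)), 0.02 + 1e-12)
  expect_error(reconstruct(v, 7), "span")
})
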