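make_cum <- function(vx, vyDp) {
  # build a cumulative set directly from a non-decreasing target sequence
  vy <- cumsum(c(0, diff(vyDp)))           # any signal with this variation
  cumulative_signal(vertex_set(vx, vy))
}

test_that("amplitude features partition the cumulative range", {
  cum <- make_cum(c(1, 5, 9, 12), c(0, 5, 8, 8))
  expect_equal(amplitude_features(cum, 1), c(AL = 0, AR = 8))
  expect_equal(amplitude_features(cum, 4), c(AL = 8, AR = 0))
  expect_equal(amplitude_features(cum, 2), c(AL = 5, AR = 3))
  expect_error(amplitude_features(cum, 9), "range")
})

test_that("time features measure distance to the 0.3 s reference points", {
  cum <- make_cum(c(1, 76, 151, 201), c(0, 1, 2, 3))
  fs <- 250
  tf <- time_features(cum, 1, fs)
  expect_equal(unname(tf["TL"]), 0.3 * fs)
  tf <- time_features(cum, 2, fs)      # exactly 0.3 s after the R-peak
  expect_equal(unname(tf["TL"]), 0)

  cum <- make_cum(c(1, 151, 201), c(0, 1, 2))
  tf <- time_features(cum, 2, 250)     # vx_1=1, vx_n=201, vx_i=151
  expect_equal(unname(tf["TL"]), -75)
  expect_equal(unname(tf["TR"]), 25)
})

test_that("vertex angles fold into [0, pi/2] with the declared axis scales", {
  cum <- make_cum(c(1, 11, 21, 31), c(0, 0, 10, 20))
  ang <- vertex_angles(cum, 2, x_scale = 10, y_scale = 10)
  expect_equal(unname(ang["thetaL"]), 0)        # flat left chord
  expect_equal(unname(ang["thetaR"]), pi / 4)   # unit normalized slope
  # onset-like staircase: flat left, steep right
  cum <- make_cum(c(1, 50, 53, 56), c(0, 0.01, 5, 10))
  ang <- vertex_angles(cum, 2, x_scale = 75, y_scale = 1)
  expect_lt(ang[["thetaL"]], 0.1)
  expect_gt(ang[["thetaR"]], pi / 2 - 0.1)
  expect_error(vertex_angles(cum, 1, 1, 1), "boundary")
})

test_that("staircase corners are detected as onset and offset", {
  fs <- 250
  # onset: [flat, flat, corner, R]; corner 40 ms (10 samples) before R
  cum_on <- make_cum(c(1, 60, 191, 201), c(0, 0.001, 0.002, 1))
  i <- detect_onset(cum_on, fs)
  expect_equal(cum_on$vx[i], 191)
  # offset mirror: corner 40 ms after R
  cum_off <- make_cum(c(1, 11, 140, 201), c(0, 0.998, 0.999, 1))
  i <- detect_offset(cum_off, fs)
  expect_equal(cum_off$vx[i], 11)
})

test_that("clean synthetic beats are delineated within two samples", {
  sim <- generate_record(beat_spec(), n_beats = 5, rr_s = 0.8, fs = 250)
  segs <- segment_rr(sim$record, sim$r_positions)
  qon <- ann_indices(sim$truth, "Qon")
  soff <- ann_indices(sim$truth, "Soff")
  for (i in seq_along(segs)) {
    seg <- segs[[i]]
    cum <- cumulative_signal(approximate(seg))
    on_i <- detect_onset(cum, 250)
    off_i <- detect_offset(cum, 250)
    expect_lte(abs(seg$start_index + cum$vx[on_i] - 1 - qon[i + 1]), 2)
    expect_lte(abs(seg$start_index + cum$vx[off_i] - 1 - soff[i]), 2)
  }
})

test_that("the selected vertex matches independent brute-force scoring", {
  sim <- generate_record(beat_spec(), n_beats = 6, rr_s = 0.8, fs = 250,
                         noise = test_noise(21))
  rec <- bandpass_filter(sim$record)
  segs <- segment_rr(rec, sim$r_positions)
  for (seg in segs) {
    cum <- cumulative_signal(approximate(seg))
    for (side in c("onset", "offset")) {
      got <- if (side == "onset") detect_onset(cum, 250)
             else detect_offset(cum, 250)
      ora <- oracle_scores(cum, 250, side)
      expect_equal(max(attr(got, "scores")$score),
                   max(ora$score), tolerance = 1e-12)
      expect_true(as.integer(got) %in% ora$i[ora$score == max(ora$score)])
    }
  }
})

test_that("weight terms stay in [0, 1] and the search window bounds hold", {
  sim <- generate_record(beat_spec(), n_beats = 6, rr_s = 0.8, fs = 250,
                         noise = test_noise(33))
  del <- delineate_record(sim$record, diagnostics = TRUE)
  for (sc2 in del$scores) {
    for (side in c("onset", "offset")) {
      sc <- sc2[[side]]
      expect_true(all(sc$wA >= 0 & sc$wA <= 1))
      expect_true(all(sc$wT >= 0 & sc$wT <= 1))
      expect_true(all(sc$wC >= 0 & sc$wC <= 1))
      expect_true(all(sc$wS >= 0 & sc$wS <= 1))
      expect_equal(sum(sc$wA == 1), 1)
    }
  }
  fid <- del$fiducials
  ok <- fid$complete
  expect_true(all(fid$q_on[ok] < fid$r[ok]))
  expect_true(all(fid$q_on[ok] >= fid$r[ok] - 0.3 * 250))
  expect_true(all(fid$s_off[ok] > fid$r[ok]))
  expect_true(all(fid$s_off[ok] <= fid$r[ok] + 0.3 * 250))
})

test_that("delineate_record emits one onset/offset per interior segment", {
  sim <- generate_record(beat_spec(), n_beats = 20, rr_s = 0.8, fs = 250)
  del <- delineate_record(sim$record)
  expect_equal(nrow(del$fiducials), 20)
  expect_equal(sum(!is.na(del$fiducials$q_on)), 19)   # first beat lacks onset
  expect_equal(sum(!is.na(del$fiducials$s_off)), 19)  # last beat lacks offset
  expect_equal(sum(del$fiducials$complete), 18)
})

test_that("beats without Q and S deflections are still delineated", {
  spec <- beat_spec(include_q = FALSE, include_s = FALSE)
  sim <- generate_record(spec, n_beats = 10, rr_s = 0.8, fs = 250)
  del <- delineate_record(sim$record)
  err <- beat_errors(del$annotations, sim$truth, 250)
  e <- err$error_ms[err$label %in% c("Qon", "Soff")]
  e <- e[!is.na(e)]
  expect_gte(length(e), 16)
  expect_true(all(abs(e) <= 10))
})

test_that("delineation is invariant under polarity flip and amplitude scaling", {
  sim <- generate_record(beat_spec(), n_beats = 8, rr_s = 0.8, fs = 250,
                         noise = test_noise(8))
  base <- delineate_record(sim$record)$fiducials
  for (f in list(function(x) -x, function(x) 3 * x)) {
    rec2 <- sim$record
    rec2$samples <- f(rec2$samples)
    got <- delineate_record(rec2)$fiducials
    expect_identical(got[c("r", "q_on", "s_off")],
                     base[c("r", "q_on", "s_off")])
  }
})

test_that("a record with no detectable beats degrades gracefully", {
  rec <- ecg_record(rep(0, 1000), fs = 250)
  expect_warning(del <- delineate_record(rec), "no R-peaks")
  expect_equal(nrow(del$fiducials), 0)
})
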