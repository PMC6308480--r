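test_that("beat errors pair nearest same-label detections within the window", {
  ref <- annotation_set(c(100, 130, 165), c("Qon", "Rpeak", "Soff"))
  expect_equal(beat_errors(ref, ref, 250)$error_ms, c(0, 0, 0))

  det <- annotation_set(c(102, 132, 167), c("Qon", "Rpeak", "Soff"))
  e <- beat_errors(det, ref, 250)
  expect_equal(e$error_ms, c(8, 8, 8))   # 2 samples late at 250 Hz
})

test_that("references beyond the matching window stay unmatched", {
  ref <- annotation_set(100, "Qon")
  det <- annotation_set(150, "Qon")    # 200 ms away at 250 Hz
  e <- beat_errors(det, ref, 250, match_window_ms = 150)
  expect_true(is.na(e$det_index))
  expect_true(is.na(e$error_ms))
  expect_error(beat_errors(det, ref, -1), "positive")
})

test_that("errors negate when detected and reference swap roles", {
  ref <- annotation_set(c(100, 300, 500), rep("Qon", 3))
  det <- annotation_set(c(98, 305, 501), rep("Qon", 3))
  a <- beat_errors(det, ref, 250)$error_ms
  b <- beat_errors(ref, det, 250)$error_ms
  expect_equal(a, -b)
})

test_that("record statistics use the sample (n-1) standard deviation", {
  s <- record_stats(c(-4, -4, -4))
  expect_equal(unname(s["mean_ms"]), -4)
  expect_equal(unname(s["sd_ms"]), 0)

  s <- record_stats(c(0, 8))
  expect_equal(unname(s["mean_ms"]), 4)
  expect_equal(unname(s["sd_ms"]), sqrt(32))   # 5.657 with n-1 denominator

  expect_true(is.na(record_stats(c(3))["sd_ms"]))
  set.seed(1)
  e <- rnorm(20)
  expect_equal(record_stats(e), record_stats(sample(e)))
})

test_that("aggregation is the unweighted mean of per-record statistics", {
  pr <- data.frame(mean_ms = c(0, 4), sd_ms = c(2, 6))
  agg <- aggregate_stats(pr)
  expect_equal(unname(agg["mu_ms"]), 2)
  expect_equal(unname(agg["sigma_ms"]), 4)
  expect_equal(aggregate_stats(pr[1, , drop = FALSE]),
               c(mu_ms = 0, sigma_ms = 2))
  expect_error(aggregate_stats(pr[0, ]), "no per-record")
})

test_that("channel selection uses the |mean| + sd criterion", {
  s1 <- data.frame(record = c("r1", "r2", "r3"),
                   mean_ms = c(-2, 0, 1), sd_ms = c(5, 10, 2))
  s2 <- data.frame(record = c("r1", "r2"),
                   mean_ms = c(-10, -6), sd_ms = c(9, 3))
  bc <- best_channel(s1, s2)
  expect_equal(bc$channel[bc$record == "r1"], 1L)   # 7 vs 19: dominated
  expect_equal(bc$channel[bc$record == "r2"], 2L)   # 10 vs 9
  expect_true(bc$flagged[bc$record == "r3"])        # single-channel record
  tie <- best_channel(s1[1, ], s1[1, ])
  expect_equal(tie$channel, 1L)                     # deterministic tie-break
})

test_that("QR/RS section statistics separate widened beats", {
  fid <- data.frame(beat = 1:4, r = c(100, 300, 500, 700),
                    q_on = c(100, 300, 500, 700) - 25,
                    s_off = c(100, 300, 500, 700) + 30,
                    complete = TRUE)
  st <- section_stats(fid, fs = 250)
  expect_equal(st$qr_mean_ms, 100)
  expect_equal(st$qr_sd_ms, 0)
  expect_equal(st$rs_mean_ms, 120)

  labs <- c("N", "N", "V", "V")
  fid$q_on[3:4] <- fid$r[3:4] - 50          # widened QR for the PVC group
  st <- section_stats(fid, 250, labs)
  expect_gt(st$qr_mean_ms[st$label == "V"], st$qr_mean_ms[st$label == "N"])

  st <- section_stats(fid, 250, labs, min_count = 30)
  expect_equal(nrow(st), 0)                 # sparse labels dropped
})

test_that("tolerance checking is boundary-inclusive against CSE limits", {
  v <- check_tolerance(6.5, 11.6)
  expect_true(v[["onset"]]); expect_true(v[["offset"]])
  expect_false(check_tolerance(6.51, 11.7)[["offset"]])
  # an onset sigma just under 8 ms still fails the 6.5 ms onset tolerance
  expect_false(check_tolerance(7.99, 8.04)[["onset"]])
  expect_true(check_tolerance(7.99, 8.04)[["offset"]])
})
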