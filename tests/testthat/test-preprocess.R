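test_that("window count matches brute-force enumeration", {
  brute_count <- function(len, w, s) {
    n <- 0L; a <- 0L
    while (a + w <= len) { n <- n + 1L; a <- a + s }
    n
  }
  set.seed(31)
  for (i in 1:60) {
    len <- sample(0:1000, 1)
    w <- sample(1:60, 1)
    s <- sample(1:w, 1)
    expect_identical(length(myograsp:::window_starts(len, w, s)),
                     brute_count(len, w, s),
                     info = sprintf("len=%d w=%d s=%d", len, w, s))
  }
})

test_that("slice_windows implements the documented count and anchoring", {
  rec <- tiny_recording(matrix(seq_len(2 * 400) / 100, 2, 400),
                        rep(1, 400))
  # 200-sample segment, W=10, S=5 (50/25 ms at 200 Hz) -> 39 windows
  wins <- slice_windows(rec, window_spec(50, 25), c(0L, 200L))
  expect_length(wins, 39)
  expect_identical(vapply(wins, `[[`, numeric(1), "start"),
                   as.numeric(seq(0, 190, by = 5)))
  expect_identical(dim(wins[[1]]$emg), c(2L, 10L))
  # segment length == W -> 1 window; == W - 1 -> 0 windows
  expect_length(slice_windows(rec, window_spec(50, 25), c(0L, 10L)), 1)
  expect_length(slice_windows(rec, window_spec(50, 25), c(0L, 9L)), 0)
  # windows anchor at the segment start
  w2 <- slice_windows(rec, window_spec(50, 25), c(13L, 33L))
  expect_identical(w2[[1]]$start, 13L)
  expect_identical(w2[[1]]$force, rec$force[14:23])
})

test_that("force feature is the window mean", {
  expect_identical(force_feature(rep(27, 10)), 27)
  expect_identical(force_feature(c(0, 10)), 5)
  expect_error(force_feature(numeric(0)), "empty")
})

test_that("force quantizer uses half-open 5 N bins with a closed top", {
  s <- level_scheme()
  expect_identical(quantize_force(27, s), 6L)    # 25-30 N bin
  expect_identical(quantize_force(0, s), 1L)
  expect_identical(quantize_force(40, s), 8L)
  expect_identical(quantize_force(5, s), 2L)     # shared edge goes up
  expect_identical(quantize_force(4.999, s), 1L)
  expect_error(quantize_force(40.5, s), "40.5")
  expect_error(quantize_force(-1, s), "-1")
  # quantizing bin midpoints recovers every level
  expect_identical(quantize_force(level_midpoint(1:8, s), s), 1:8)
})

test_that("activity detection follows the summed-MAV threshold rule", {
  spec <- window_spec()
  # all-zero sEMG: no segments at any positive threshold
  rec0 <- tiny_recording(matrix(0, 8, 300), rep(0, 300))
  expect_length(detect_activity(rec0, spec, threshold = 1e-9), 0)
  # constant |x| = c on 8 channels: summed MAV = 8c; threshold 8c/2
  # is exceeded everywhere -> one segment spanning the whole recording
  recc <- tiny_recording(matrix(0.5, 8, 300), rep(0, 300))
  segs <- detect_activity(recc, spec, threshold = 8 * 0.5 / 2)
  expect_length(segs, 1)
  expect_identical(segs[[1]], c(0L, 300L))
  # recording shorter than one window: empty result, not an error
  expect_length(detect_activity(tiny_recording(matrix(1, 8, 5), rep(0, 5)),
                                spec, threshold = 1), 0)
  expect_error(detect_activity(recc, spec, threshold = -1), "positive")
})

test_that("detection recovers the generated activity interval", {
  p <- subject_profile()
  cfg <- short_config()
  spec <- window_spec()
  for (lv in c(2, 6)) {
    rec <- generate_session(p, cfg, level = lv, seed = 70 + lv)
    segs <- detect_activity(rec, spec, default_onset_threshold(rec, spec))
    expect_length(segs, 1)
    truth <- rec$metadata$active_interval
    w <- 0.05 * rec$sampling_rate                # one window length
    expect_lte(abs(segs[[1]][1] - truth[1]), w)
    expect_lte(abs(segs[[1]][2] - truth[2]), w)
    # the segment covers the hold plateau
    hold <- rec$metadata$hold_interval
    expect_lte(segs[[1]][1], hold[1])
    expect_gte(segs[[1]][2], hold[2])
  }
})

test_that("window spec validates sample alignment", {
  expect_error(window_spec(50, 60), "step_ms")
  expect_error(window_spec(0, 0), "step_ms")
  rec <- tiny_recording(matrix(1, 2, 100), rep(0, 100))
  expect_error(slice_windows(rec, window_spec(51, 17)), "whole sample")
})
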