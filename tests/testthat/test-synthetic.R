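test_that("equal seeds and arguments give bit-identical recordings", {
  p <- subject_profile()
  cfg <- short_config()
  a <- generate_session(p, cfg, level = 3, seed = 99)
  b <- generate_session(p, cfg, level = 3, seed = 99)
  expect_identical(a, b)
  c <- generate_session(p, cfg, level = 3, seed = 100)
  expect_false(identical(a$emg, c$emg))
})

test_that("force plateau lies inside the requested level's bin", {
  p <- subject_profile()
  cfg <- short_config()
  for (lv in c(1, 4, 6, 8)) {
    rec <- generate_session(p, cfg, level = lv, seed = 7 + lv)
    lo <- 5 * (lv - 1); hi <- 5 * lv
    expect_gte(rec$metadata$plateau_force, lo)
    expect_lte(rec$metadata$plateau_force, hi)
    hold <- rec$metadata$hold_interval
    plateau_force <- rec$force[(hold[1] + 1):hold[2]]
    expect_true(all(plateau_force > lo - 1 & plateau_force < hi + 1))
  }
  # level 6 example: plateau within 25-30 N
  rec6 <- generate_session(p, cfg, level = 6, seed = 123)
  expect_true(rec6$metadata$plateau_force >= 25 &&
              rec6$metadata$plateau_force <= 30)
})

test_that("zero baseline noise and zero force give identically zero sEMG", {
  p <- clean_profile(baseline_noise_sd = 0)
  rec <- generate_session(p, short_config(), level = 1, seed = 5,
                          plateau_force = 0)
  expect_true(all(rec$emg == 0))
  expect_true(all(rec$force == 0))
})

test_that("mean rectified hold amplitude increases strictly with level", {
  p <- clean_profile()
  cfg <- short_config()
  amp <- sapply(1:8, function(lv) {
    rec <- generate_session(p, cfg, level = lv, seed = 40 + lv)
    hold <- rec$metadata$hold_interval
    rowMeans(abs(rec$emg[, (hold[1] + 1):hold[2]]))
  })
  for (ch in 1:8) expect_true(all(diff(amp[ch, ]) > 0))
})

test_that("rest stays below and hold above the default onset threshold", {
  p <- subject_profile()
  cfg <- short_config()
  spec <- window_spec()
  for (lv in c(1, 8)) {
    rec <- generate_session(p, cfg, level = lv, seed = 60 + lv)
    thr <- default_onset_threshold(rec, spec)
    hold <- rec$metadata$hold_interval
    smav <- function(interval) {
      wins <- slice_windows(rec, spec, interval)
      vapply(wins, function(w) sum(rowMeans(abs(w$emg))), numeric(1))
    }
    expect_true(all(smav(c(0, rec$metadata$active_interval[1])) < thr))
    expect_true(all(smav(hold) >= thr))
  }
})

test_that("cohort generation is deterministic and covers all levels", {
  cfg <- short_config()
  cohort <- generate_cohort(2, cfg, seed = 17)
  expect_length(cohort, 2)
  for (subj in cohort) {
    expect_s3_class(subj$profile, "subject_profile")
    expect_length(subj$sessions, 8)  # one repetition per level
    expect_setequal(vapply(subj$sessions, `[[`, integer(1), "level_label"),
                    1:8)
  }
  again <- generate_cohort(2, cfg, seed = 17)
  expect_identical(cohort[[1]]$profile, again[[1]]$profile)
  expect_identical(cohort[[2]]$sessions[[5]], again[[2]]$sessions[[5]])
  # profiles differ between subjects
  expect_false(identical(cohort[[1]]$profile$channel_gains,
                         cohort[[2]]$profile$channel_gains))
})

test_that("generator validates its inputs", {
  p <- subject_profile()
  cfg <- short_config()
  expect_error(generate_session(p, cfg, level = 0, seed = 1), "level")
  expect_error(generate_session(p, cfg, level = 9, seed = 1), "level")
  expect_error(generate_session(p, cfg, level = 2), "seed")
  expect_error(acquisition_config(hold_duration = c(-1, 2)), "hold_duration")
  expect_error(acquisition_config(force_range = c(40, 0)), "force_range")
  expect_error(subject_profile(channel_gains = rep(1, 7)), "8 positive")
  expect_error(subject_profile(baseline_noise_sd = -1), "non-negative")
})
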