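test_that("centroid defuzzification matches a dense-grid oracle", {
  cfg <- fuzzy_config()
  grid_centroid <- function(terms, act, universe, n = 200001) {
    xs <- seq(universe[1], universe[2], length.out = n)
    mu <- rep(0, n)
    for (i in seq_along(act)) if (act[i] > 0)
      mu <- pmax(mu, pmin(myograsp:::trimf(xs, terms[i, ]), act[i]))
    if (sum(mu) == 0) return(mean(universe))
    sum(xs * mu) / sum(mu)
  }
  set.seed(61)
  for (i in 1:10) {
    act <- runif(5) * rbinom(5, 1, 0.7)
    exact <- myograsp:::centroid_defuzz(cfg$output_terms, act,
                                        cfg$output_universe)
    oracle <- grid_centroid(cfg$output_terms, pmin(act, 1),
                            cfg$output_universe)
    expect_lt(abs(exact - oracle), 1e-6)
    expect_gte(exact, cfg$output_universe[1])
    expect_lte(exact, cfg$output_universe[2])
  }
})

test_that("the symmetric rulebase is quiet at zero error and pushes on demand", {
  cfg <- fuzzy_config()
  expect_equal(fuzzy_step(cfg, 0, 0), 0, tolerance = 1e-12)
  big <- fuzzy_step(cfg, 35, 0)
  expect_gt(big, 0.5 * cfg$output_universe[2])   # upper region of universe
  expect_lt(fuzzy_step(cfg, -35, 0), 0.5 * cfg$output_universe[1])
  # inputs beyond the universe are clipped, not errors
  expect_equal(fuzzy_step(cfg, 1e6, -1e6), fuzzy_step(cfg, 40, -5))
})

test_that("fuzzy configuration validates coverage and rulebase totality", {
  expect_error(fuzzy_config(rulebase = matrix(9, 5, 5)), "total")
  bad_terms <- myograsp:::default_terms(c(-40, 40))
  bad_terms[3, ] <- c(5, 6, 7)                   # leaves a hole at 0 N
  expect_error(fuzzy_config(error_terms = bad_terms), "cover")
})

test_that("the plant follows its first-order closed form", {
  st <- plant_state(grip_force = 0, time_constant = 0.2, gain = 40)
  # command 0 from rest: stays at rest
  expect_identical(plant_step(st, 0, 0.01)$state$grip_force, 0)
  # constant command: discrete trajectory approaches gain * command and
  # matches the exact exponential solution to O(dt)
  dt <- 1e-3
  f <- 0; traj <- numeric(2000)
  for (i in 1:2000) {
    stp <- plant_step(plant_state(f, 0.2, 40), 0.3, dt)
    f <- stp$state$grip_force
    traj[i] <- f
  }
  t_end <- 2000 * dt
  exact <- 40 * 0.3 * (1 - exp(-seq(dt, t_end, dt) / 0.2))
  expect_lt(max(abs(traj - exact)), 0.1)         # O(dt) agreement
  expect_equal(f, 12, tolerance = 1e-3)          # fixed point gain * command
  expect_error(plant_step(st, 1, dt = 0), "dt")
  expect_error(plant_state(grip_force = -1), "grip_force")
})

test_that("vibration feedback quantizes and maps strictly increasing", {
  s <- level_scheme()
  v <- vibration_level(27, s)
  expect_identical(v$level, 6L)                  # 25-30 N bin
  freqs <- vapply(level_midpoint(1:8, s),
                  function(f) vibration_level(f, s)$frequency_hz, numeric(1))
  expect_true(all(diff(freqs) > 0))
  expect_identical(vibration_level(-3, s)$level, 1L)  # clipped noise
  expect_identical(vibration_level(99, s)$level, 8L)
})

test_that("a matched setpoint produces near-zero commands throughout", {
  tr <- run_grasp(20, plant = plant_state(grip_force = 20), duration = 2,
                  seed = 2)
  expect_lt(max(abs(tr$trace$command - 20 / 40)), 0.02)
  expect_lt(tr$steady_state_error, 0.1)
})

test_that("noise-free steps settle with small steady-state error", {
  tr <- run_grasp(20, duration = 5, seed = 3)
  expect_lt(tr$steady_state_error, 0.5)
  expect_true(tr$converged)
  expect_identical(nrow(tr$trace), 500L)         # duration / dt bookkeeping
  for (sp in seq(5, 40, by = 5)) {
    tr <- run_grasp(sp, duration = 5, seed = 3)
    expect_lt(tr$steady_state_error, 2.5)
  }
})

test_that("the loop is rate-stable and the trace is consistent", {
  tr1 <- run_grasp(15, duration = 4, dt = 0.01, seed = 5)
  tr2 <- run_grasp(15, duration = 4, dt = 0.005, seed = 5)
  expect_lt(abs(tail(tr1$trace$force_N, 1) - tail(tr2$trace$force_N, 1)), 1)
  # vibration level tracks the sensed force
  i <- nrow(tr1$trace)
  expect_identical(tr1$trace$vibration_level[i],
                   vibration_level(tr1$trace$sensed_N[i])$level)
  expect_error(run_grasp(45), "outside")
  # midpoint mode regulates to the bin midpoint
  tr3 <- run_grasp(27, duration = 5, seed = 7, setpoint_mode = "midpoint")
  expect_identical(tr3$trace$setpoint[1], 27.5)
})
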