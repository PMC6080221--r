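# Simulated closed grasp loop: the predicted force is the setpoint, a
# Mamdani fuzzy controller outputs grip-command increments, the hand is a
# first-order lag plant, an FSR-style sensor (optionally noisy) closes
# the loop, and the sensed force is quantized to a vibrotactile level.
#
# The controller design (5 triangular terms per input, symmetric 25-rule
# PD-style rulebase, centroid defuzzification) is conventional; every
# choice is surfaced in the config and overridable.

# Triangular membership with shoulders: a == b makes a left shoulder
# (mu = 1 for x <= b), b == c a right shoulder.
trimf <- function(x, abc) {
  a <- abc[1]; b <- abc[2]; c <- abc[3]
  up <- if (b > a) (x - a) / (b - a) else as.numeric(x >= b)
  dn <- if (c > b) (c - x) / (c - b) else as.numeric(x <= b)
  pmax(pmin(up, dn, 1), 0)
}

# 5 evenly spaced triangles (NB, NS, Z, PS, PB) over [lo, hi], shouldered
# at the ends so the whole universe is covered.
default_terms <- function(universe) {
  lo <- universe[1]; hi <- universe[2]
  ctr <- seq(lo, hi, length.out = 5)
  h <- (hi - lo) / 4
  t(vapply(seq_len(5), function(i)
    c(max(lo, ctr[i] - h), ctr[i], min(hi, ctr[i] + h)), numeric(3)))
}

#' Mamdani fuzzy controller configuration
#'
#' @param error_universe force-error universe (N).
#' @param derror_universe error-change universe (N per step).
#' @param output_universe command-increment universe (actuator units per
#'   step).
#' @param error_terms,derror_terms,output_terms 5 x 3 matrices of
#'   triangle knots `(a, b, c)` per term, ordered NB, NS, Z, PS, PB;
#'   defaults are evenly spaced shouldered triangles over the universes.
#' @param rulebase 5 x 5 integer matrix: output term index for each
#'   (error term, derror term) pair. Default: the symmetric PD rulebase
#'   `clamp(i + j - 3, 1, 5)`.
#' @return an object of class `fuzzy_config`.
#' @export
fuzzy_config <- function(error_universe = c(-40, 40),
                         derror_universe = c(-5, 5),
                         output_universe = c(-0.04, 0.04),
                         error_terms = default_terms(error_universe),
                         derror_terms = default_terms(derror_universe),
                         output_terms = default_terms(output_universe),
                         rulebase = NULL) {
  if (is.null(rulebase))
    rulebase <- outer(1:5, 1:5, function(i, j) pmin(pmax(i + j - 3, 1), 5))
  for (tm in list(error_terms, derror_terms, output_terms))
    if (!is.matrix(tm) || ncol(tm) != 3L)
      stop_validation("term matrices must have 3 columns (a, b, c)")
  if (!all(dim(rulebase) == c(nrow(error_terms), nrow(derror_terms))) ||
      any(rulebase < 1 | rulebase > nrow(output_terms)))
    stop_validation("rulebase must be total over the term grid")
  cfg <- structure(list(error_universe = error_universe,
                        derror_universe = derror_universe,
                        output_universe = output_universe,
                        error_terms = error_terms,
                        derror_terms = derror_terms,
                        output_terms = output_terms,
                        rulebase = rulebase),
                   class = "fuzzy_config")
  # coverage: every input in the universe must activate at least one term
  for (nm in c("error", "derror", "output")) {
    u <- cfg[[paste0(nm, "_universe")]]
    tm <- cfg[[paste0(nm, "_terms")]]
    xs <- seq(u[1], u[2], length.out = 101)
    cover <- Reduce(pmax, lapply(seq_len(nrow(tm)),
                                 function(i) trimf(xs, tm[i, ])))
    if (any(cover <= 0))
      stop_validation(nm, " terms do not cover their universe")
  }
  cfg
}

# Exact centroid of the aggregated (max of clipped triangles) membership.
# The aggregate is piecewise linear; breakpoints are term knots, clip
# corners, and pairwise crossings, so trapezoidal integration over the
# final partition is exact.
centroid_defuzz <- function(terms, activations, universe) {
  act <- pmin(activations, 1)
  keep <- which(act > 0)
  if (length(keep) == 0L) return(mean(universe))
  xs <- c(universe)
  for (i in keep) {
    abc <- terms[i, ]; a <- act[i]
    xs <- c(xs, abc)
    if (a < 1) {                      # clip corners on each edge
      if (abc[2] > abc[1]) xs <- c(xs, abc[1] + a * (abc[2] - abc[1]))
      if (abc[3] > abc[2]) xs <- c(xs, abc[3] - a * (abc[3] - abc[2]))
    }
  }
  xs <- sort(unique(pmin(pmax(xs, universe[1]), universe[2])))
  mu_at <- function(x) {
    vals <- matrix(vapply(keep, function(i) pmin(trimf(x, terms[i, ]), act[i]),
                          numeric(length(x))), nrow = length(x))
    apply(vals, 1, max)
  }
  # insert pairwise crossings of the linear pieces inside each interval
  extra <- numeric(0)
  for (s in seq_len(length(xs) - 1L)) {
    x0 <- xs[s]; x1 <- xs[s + 1L]
    if (x1 - x0 < 1e-12) next
    v0 <- vapply(keep, function(i) min(trimf(x0, terms[i, ]), act[i]),
                 numeric(1))
    v1 <- vapply(keep, function(i) min(trimf(x1, terms[i, ]), act[i]),
                 numeric(1))
    for (i in seq_along(keep)) for (j in seq_along(keep)) {
      if (i >= j) next
      d0 <- v0[i] - v0[j]; d1 <- v1[i] - v1[j]
      if (d0 * d1 < 0)
        extra <- c(extra, x0 + (x1 - x0) * d0 / (d0 - d1))
    }
  }
  xs <- sort(unique(c(xs, extra)))
  mu <- mu_at(xs)
  dx <- diff(xs)
  m0 <- sum(dx * (mu[-length(mu)] + mu[-1]) / 2)
  if (m0 <= 0) return(mean(universe))
  # exact first moment of x * mu(x) with mu linear on each piece
  x0 <- xs[-length(xs)]; x1 <- xs[-1]
  y0 <- mu[-length(mu)]; y1 <- mu[-1]
  m1 <- sum(dx * (x0 * (2 * y0 + y1) + x1 * (y0 + 2 * y1)) / 6)
  m1 / m0
}

#' One Mamdani inference step
#'
#' Fuzzifies error and error-change (inputs clipped to their universes),
#' evaluates the rulebase with min-AND / max-aggregation, and returns the
#' centroid-defuzzified command increment.
#'
#' @param cfg a [fuzzy_config()].
#' @param error force error (N).
#' @param derror change of the error since the previous step (N/step).
#' @return command increment, inside the output universe.
#' @export
fuzzy_step <- function(cfg, error, derror) {
  stopifnot(inherits(cfg, "fuzzy_config"), is.finite(error), is.finite(derror))
  e <- clamp(error, cfg$error_universe[1], cfg$error_universe[2])
  de <- clamp(derror, cfg$derror_universe[1], cfg$derror_universe[2])
  me <- vapply(seq_len(nrow(cfg$error_terms)),
               function(i) trimf(e, cfg$error_terms[i, ]), numeric(1))
  md <- vapply(seq_len(nrow(cfg$derror_terms)),
               function(i) trimf(de, cfg$derror_terms[i, ]), numeric(1))
  n_out <- nrow(cfg$output_terms)
  act <- numeric(n_out)
  for (i in seq_along(me)) for (j in seq_along(md)) {
    w <- min(me[i], md[j])
    k <- cfg$rulebase[i, j]
    if (w > act[k]) act[k] <- w
  }
  centroid_defuzz(cfg$output_terms, act, cfg$output_universe)
}

#' First-order grip plant state
#'
#' @param grip_force current grip force (N, >= 0).
#' @param time_constant actuator time constant (s).
#' @param gain steady-state force per unit command (N per actuator unit).
#' @param sensor_noise_sd SD of the FSR sensor noise (N).
#' @return an object of class `plant_state`.
#' @export
plant_state <- function(grip_force = 0, time_constant = 0.15, gain = 40,
                        sensor_noise_sd = 0) {
  if (grip_force < 0) stop_validation("grip_force must be >= 0")
  if (time_constant <= 0) stop_validation("time_constant must be > 0")
  structure(list(grip_force = grip_force, time_constant = time_constant,
                 gain = gain, sensor_noise_sd = sensor_noise_sd),
            class = "plant_state")
}

#' Advance the grip plant one step
#'
#' First-order lag toward `gain * command`, floored at zero force; the
#' sensed (FSR) force adds Gaussian noise.
#'
#' @param state a [plant_state()].
#' @param command actuator command (units).
#' @param dt step length (s, > 0).
#' @param seed optional seed for the sensor noise; `NULL` uses the
#'   ambient RNG stream (as inside [run_grasp()], which seeds it once).
#' @return list with the updated `state` and `sensed` force (N).
#' @export
plant_step <- function(state, command, dt, seed = NULL) {
  stopifnot(inherits(state, "plant_state"))
  if (dt <= 0) stop_validation("dt must be > 0")
  f <- state$grip_force +
    (dt / state$time_constant) * (state$gain * command - state$grip_force)
  state$grip_force <- max(f, 0)
  noise <- if (state$sensor_noise_sd > 0) {
    if (is.null(seed)) stats::rnorm(1, 0, state$sensor_noise_sd)
    else with_seed(seed, stats::rnorm(1, 0, state$sensor_noise_sd))
  } else 0
  list(state = state, sensed = state$grip_force + noise)
}

#' Vibrotactile feedback level and frequency
#'
#' The sensed force is clipped to the scheme's range and quantized to its
#' level; levels map to strictly increasing vibration frequencies
#' (level L -> 50 + 25 (L - 1) Hz; the mapping is a documented
#' convention, only its strict monotonicity matters).
#'
#' @param sensed_force sensed force (N, any value; clipped).
#' @param scheme a [level_scheme()].
#' @return list with `level` and `frequency_hz`.
#' @export
vibration_level <- function(sensed_force, scheme = level_scheme()) {
  f <- clamp(sensed_force, scheme$force_min, scheme$force_max)
  lv <- quantize_force(f, scheme)
  list(level = lv, frequency_hz = 50 + 25 * (lv - 1))
}

#' Simulate a closed-loop grasp
#'
#' Runs the fuzzy loop: error between setpoint and sensed force drives
#' command increments, the command (clipped to `command_range`) drives
#' the plant, and the sensed force is fed back and quantized to a
#' vibration level each step.
#'
#' @param setpoint target grip force (N), e.g. a [predict_force()] output;
#'   with `setpoint_mode = "midpoint"` the setpoint is replaced by the
#'   midpoint of its force-level bin.
#' @param cfg a [fuzzy_config()].
#' @param plant a [plant_state()].
#' @param scheme a [level_scheme()].
#' @param duration simulated time (s).
#' @param dt step length (s).
#' @param seed seed for the sensor noise stream.
#' @param command_range actuator command clip range.
#' @param setpoint_mode `"continuous"` (default) or `"midpoint"`.
#' @return an object of class `control_trace`: data frame `trace` (time,
#'   setpoint, command, plant force, sensed force, vibration level) plus
#'   `settling_time` (s; first entry into the +/-5% band around the
#'   setpoint without later exit, NA if never), `steady_state_error`
#'   (mean |setpoint - force| over the final 10%), and `converged`.
#' @export
run_grasp <- function(setpoint, cfg = fuzzy_config(), plant = plant_state(),
                      scheme = level_scheme(), duration = 5, dt = 0.01,
                      seed = 1L, command_range = c(0, 1.5),
                      setpoint_mode = c("continuous", "midpoint")) {
  setpoint_mode <- match.arg(setpoint_mode)
  if (setpoint < scheme$force_min || setpoint > scheme$force_max)
    stop_validation("setpoint outside the scheme's force range")
  if (setpoint_mode == "midpoint")
    setpoint <- level_midpoint(quantize_force(setpoint, scheme), scheme)
  n <- as.integer(round(duration / dt))
  trace <- data.frame(time_s = (seq_len(n) - 1) * dt, setpoint = setpoint,
                      command = NA_real_, force_N = NA_real_,
                      sensed_N = NA_real_, vibration_level = NA_integer_)
  with_seed(seed, {
    command <- plant$grip_force / plant$gain    # start at plant equilibrium
    sensed <- plant$grip_force
    e_prev <- setpoint - sensed
    for (i in seq_len(n)) {
      e <- setpoint - sensed
      command <- clamp(command + fuzzy_step(cfg, e, e - e_prev),
                       command_range[1], command_range[2])
      e_prev <- e
      step <- plant_step(plant, command, dt)
      plant <- step$state
      sensed <- step$sensed
      trace$command[i] <- command
      trace$force_N[i] <- plant$grip_force
      trace$sensed_N[i] <- sensed
      trace$vibration_level[i] <- vibration_level(sensed, scheme)$level
    }
  })
  tol <- max(0.05 * abs(setpoint), 0.25)
  inside <- abs(trace$force_N - setpoint) <= tol
  settled_at <- NA_real_
  if (any(inside)) {
    stays <- rev(cumprod(rev(inside))) > 0   # inside from here to the end
    if (any(stays)) settled_at <- trace$time_s[which(stays)[1]]
  }
  tail_idx <- seq.int(max(1L, n - ceiling(0.1 * n) + 1L), n)
  structure(list(trace = trace,
                 settling_time = settled_at,
                 steady_state_error = mean(abs(setpoint -
                                               trace$force_N[tail_idx])),
                 converged = !is.na(settled_at)),
            class = "control_trace")
}

#' @export
print.control_trace <- function(x, ...) {
  cat(sprintf(paste0("<control_trace> %d steps, settling %.2f s, ",
                     "steady-state error %.3f N (%s)\n"),
              nrow(x$trace), x$settling_time, x$steady_state_error,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Write a control trace as CSV
#' @param x a `control_trace`.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_control_trace <- function(x, path) {
  utils::write.csv(x$trace, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
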