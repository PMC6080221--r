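# Synthetic sEMG/force acquisition. Emulates an 8-channel armband protocol:
# repeated pinch holds at one of 8 force levels spanning 0-40 N, separated
# by rest, with per-subject channel gains and per-trial gain jitter.
#
# Signal model (documented in the methods vignette): each channel is
# zero-mean white noise multiplied by a deterministic envelope
#   env_c(t) = baseline_noise_sd + gain_c * jitter_c * m(F(t)),
# with recruitment curve m(F) = floor + (1 - floor) * (F / Fmax)^q for
# F > 0 and m(0) = 0. The default carrier has stabilized amplitude
# (sign * |1 + cv * z|), emulating device-conditioned sEMG whose
# short-window amplitude is steady at constant force; a raw Gaussian
# carrier is available via `carrier = "gaussian"`.

#' Subject profile for the synthetic generator
#'
#' @param subject_id identifier.
#' @param channel_gains 8 positive per-channel sEMG scale factors (unitless).
#' @param gain_jitter SD of the multiplicative per-trial gain noise.
#' @param baseline_noise_sd rest-state sEMG envelope (signal units).
#' @param force_tremor_sd SD of the plateau force tremor (N).
#' @param amplitude_cv amplitude coefficient of variation of the stabilized
#'   broadband carrier (dimensionless).
#' @param activation_floor envelope jump at grip onset, as a fraction of the
#'   full-scale drive (captures recruitment at light pinch).
#' @param recruitment_exponent exponent of the envelope-force power law.
#' @return an object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id = "S01",
                            channel_gains = rep(1, 8),
                            gain_jitter = 0.02,
                            baseline_noise_sd = 0.008,
                            force_tremor_sd = 0.3,
                            amplitude_cv = 0.08,
                            activation_floor = 0.05,
                            recruitment_exponent = 2) {
  channel_gains <- as.numeric(channel_gains)
  if (length(channel_gains) != 8L || any(channel_gains <= 0))
    stop_validation("channel_gains must be 8 positive scalars")
  for (v in c(gain_jitter, baseline_noise_sd, force_tremor_sd, amplitude_cv))
    if (!is.numeric(v) || length(v) != 1L || v < 0)
      stop_validation("noise parameters must be non-negative scalars")
  if (activation_floor < 0 || activation_floor >= 1)
    stop_validation("activation_floor must lie in [0, 1)")
  if (recruitment_exponent <= 0)
    stop_validation("recruitment_exponent must be positive")
  structure(list(subject_id = as.character(subject_id),
                 channel_gains = channel_gains,
                 gain_jitter = gain_jitter,
                 baseline_noise_sd = baseline_noise_sd,
                 force_tremor_sd = force_tremor_sd,
                 amplitude_cv = amplitude_cv,
                 activation_floor = activation_floor,
                 recruitment_exponent = recruitment_exponent),
            class = "subject_profile")
}

#' Acquisition protocol settings
#'
#' Defaults follow the armband protocol the pipeline assumes: 200 Hz
#' sampling, 8 force levels over 0-40 N, pinch holds of 4-6 s separated
#' by rest.
#'
#' @param sampling_rate Hz.
#' @param n_levels number of grasp-force levels.
#' @param force_range numeric length-2, force span in newtons.
#' @param hold_duration numeric length-2, uniform range of hold durations (s).
#' @param rest_duration rest before and after the hold (s).
#' @param repetitions_per_level holds generated per level and subject.
#' @param ramp_duration grip onset/release ramp duration (s); pinch onset is
#'   fast, so the default is one analysis window (50 ms).
#' @param plateau_margin plateau values are drawn uniformly inside the level
#'   bin, inset from each bin edge by this fraction of the bin width.
#' @param carrier `"stabilized"` (default) or `"gaussian"` broadband carrier.
#' @return an object of class `acquisition_config`.
#' @export
acquisition_config <- function(sampling_rate = 200,
                               n_levels = 8,
                               force_range = c(0, 40),
                               hold_duration = c(4, 6),
                               rest_duration = 1,
                               repetitions_per_level = 6,
                               ramp_duration = 0.05,
                               plateau_margin = 0.05,
                               carrier = c("stabilized", "gaussian")) {
  carrier <- match.arg(carrier)
  if (sampling_rate <= 0) stop_validation("sampling_rate must be > 0")
  if (n_levels < 2) stop_validation("n_levels must be >= 2")
  if (force_range[2] <= force_range[1])
    stop_validation("force_range max must exceed min")
  if (length(hold_duration) != 2L || any(hold_duration <= 0) ||
      hold_duration[2] < hold_duration[1])
    stop_validation("hold_duration must be a positive [min, max] pair")
  if (rest_duration <= 0 || ramp_duration <= 0)
    stop_validation("durations must be positive")
  if (repetitions_per_level < 1)
    stop_validation("repetitions_per_level must be >= 1")
  if (plateau_margin < 0 || plateau_margin >= 0.5)
    stop_validation("plateau_margin must lie in [0, 0.5)")
  structure(list(sampling_rate = sampling_rate, n_levels = as.integer(n_levels),
                 force_range = as.numeric(force_range),
                 hold_duration = as.numeric(hold_duration),
                 rest_duration = rest_duration,
                 repetitions_per_level = as.integer(repetitions_per_level),
                 ramp_duration = ramp_duration,
                 plateau_margin = plateau_margin,
                 carrier = carrier),
            class = "acquisition_config")
}

# Recruitment curve: envelope drive as a monotone function of force,
# normalized to 1 at full-scale force. m(0) = 0; grip onset jumps to
# `floor` and grows as a power law above it.
recruitment_drive <- function(force, fmax, floor, exponent) {
  drive <- floor + (1 - floor) * (pmax(force, 0) / fmax)^exponent
  drive[force <= 0] <- 0
  drive
}

# Smooth tremor: AR(1)-filtered white noise with stationary SD `sd`.
ar1_tremor <- function(n, sd, phi = 0.9) {
  if (n == 0L || sd == 0) return(numeric(n))
  as.numeric(stats::filter(stats::rnorm(n, 0, sd * sqrt(1 - phi^2)),
                           phi, method = "recursive"))
}

#' Generate one synthetic pinch-hold session
#'
#' Produces synchronized sEMG and force traces: rest, a fast ramp to a
#' plateau drawn uniformly inside the requested level's force bin, a 4-6 s
#' hold with tremor, release, rest. Ground-truth hold and active intervals
#' (0-based, half-open sample indices) are recorded in the metadata.
#'
#' @param profile a [subject_profile()].
#' @param config an [acquisition_config()].
#' @param level force-level index in `1..config$n_levels`.
#' @param seed integer seed; equal seeds and arguments give bit-identical
#'   recordings.
#' @param plateau_force optional explicit plateau force (N), overriding the
#'   in-bin draw (used for controlled fixtures, e.g. force held at 0).
#' @return a [session_recording()] with `level_label = level`.
#' @export
generate_session <- function(profile, config = acquisition_config(),
                             level, seed, plateau_force = NULL) {
  stopifnot(inherits(profile, "subject_profile"),
            inherits(config, "acquisition_config"))
  if (!is.numeric(level) || length(level) != 1L || level < 1 ||
      level > config$n_levels || level != round(level))
    stop("level must be an integer in [1, ", config$n_levels, "]")
  if (missing(seed)) stop_validation("seed must be provided")
  fs <- config$sampling_rate
  fmin <- config$force_range[1]; fmax <- config$force_range[2]
  bin_w <- (fmax - fmin) / config$n_levels
  with_seed(seed, {
    lo <- fmin + (level - 1) * bin_w
    margin <- config$plateau_margin * bin_w
    plateau <- if (!is.null(plateau_force)) as.numeric(plateau_force)
               else stats::runif(1, lo + margin, lo + bin_w - margin)
    hold_s <- stats::runif(1, config$hold_duration[1], config$hold_duration[2])
    n_rest <- round(config$rest_duration * fs)
    n_ramp <- max(1L, round(config$ramp_duration * fs))
    n_hold <- round(hold_s * fs)
    ramp_up <- plateau * seq_len(n_ramp) / n_ramp
    hold <- plateau + ar1_tremor(n_hold, profile$force_tremor_sd)
    force <- c(rep(0, n_rest), ramp_up, hold, rev(ramp_up), rep(0, n_rest))
    force <- clamp(force, 0, fmax)
    S <- length(force)
    jitter <- 1 + stats::rnorm(8, 0, profile$gain_jitter)
    jitter <- pmax(jitter, 0.1)
    drive <- recruitment_drive(force, fmax, profile$activation_floor,
                               profile$recruitment_exponent)
    env <- profile$baseline_noise_sd +
      (profile$channel_gains * jitter) %o% drive
    carrier <- if (config$carrier == "stabilized") {
      sgn <- matrix(sample(c(-1, 1), 8 * S, replace = TRUE), 8, S)
      sgn * abs(1 + profile$amplitude_cv * matrix(stats::rnorm(8 * S), 8, S))
    } else {
      matrix(stats::rnorm(8 * S), 8, S)
    }
    hold_start <- n_rest + n_ramp            # 0-based half-open intervals
    session_recording(
      emg = env * carrier, force = force, sampling_rate = fs,
      subject_id = profile$subject_id, level_label = level,
      metadata = list(plateau_force = plateau,
                      hold_interval = c(hold_start, hold_start + n_hold),
                      active_interval = c(n_rest, n_rest + 2 * n_ramp + n_hold),
                      seed = seed))
  })
}

# Draw a subject profile from the documented between-subject distributions:
# lognormal per-channel gains (sdlog 0.25) around unity.
random_profile <- function(subject_id, seed) {
  with_seed(seed, {
    gains <- stats::rlnorm(8, meanlog = 0, sdlog = 0.25)
    subject_profile(subject_id = subject_id, channel_gains = gains)
  })
}

#' Generate a synthetic cohort
#'
#' Draws `n_subjects` profiles and, per subject and level,
#' `config$repetitions_per_level` sessions. The defaults give enough
#' windows per level (>= 800 at 50 ms / 25 ms windowing) to fill the
#' 400-training + 400-testing group pools per level the evaluation
#' protocol expects. Session seeds derive from `seed` via [split_seed()],
#' so regeneration with the same seed is exact.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param config an [acquisition_config()].
#' @param seed master integer seed.
#' @return list with one element per subject: `list(profile, sessions)`,
#'   where `sessions` is a list of [session_recording()]s covering all
#'   levels.
#' @export
generate_cohort <- function(n_subjects, config = acquisition_config(), seed) {
  if (n_subjects < 1) stop_validation("n_subjects must be >= 1")
  lapply(seq_len(n_subjects), function(s) {
    generate_subject(s, config, seed)
  })
}

# One subject's profile + sessions; shared by generate_cohort() and the
# per-subject streaming path in run_experiment().
generate_subject <- function(subject_index, config, seed) {
  sseed <- split_seed(seed, subject_index)
  profile <- random_profile(sprintf("S%02d", subject_index), sseed)
  sessions <- list()
  for (lv in seq_len(config$n_levels)) {
    for (rep in seq_len(config$repetitions_per_level)) {
      sessions[[length(sessions) + 1L]] <-
        generate_session(profile, config, lv,
                         seed = split_seed(sseed, lv * 1000L + rep))
    }
  }
  list(profile = profile, sessions = sessions)
}
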