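# Segmentation and labeling: onset detection from summed MAV, overlapping
# sliding windows, per-window force feature and level quantization.
# Conventions (used throughout): 0-based, half-open sample intervals;
# windows are anchored at the detected segment start; trailing partial
# windows are discarded.

#' Overlapping sliding-window settings
#'
#' @param window_ms analysis window length (ms), default 50.
#' @param step_ms sliding increment (ms), default 25.
#' @return an object of class `window_spec`.
#' @export
window_spec <- function(window_ms = 50, step_ms = 25) {
  if (step_ms <= 0 || window_ms <= 0 || step_ms > window_ms)
    stop_validation("need 0 < step_ms <= window_ms")
  structure(list(window_ms = window_ms, step_ms = step_ms),
            class = "window_spec")
}

# Window / step in samples at a given rate; both must be whole sample
# counts, and a window must be at least one sample.
window_samples <- function(spec, sampling_rate) {
  w <- spec$window_ms * sampling_rate / 1000
  s <- spec$step_ms * sampling_rate / 1000
  if (abs(w - round(w)) > 1e-9 || abs(s - round(s)) > 1e-9)
    stop_validation("window/step (", spec$window_ms, "/", spec$step_ms,
                    " ms) are not whole sample counts at ", sampling_rate,
                    " Hz")
  c(window = max(1L, as.integer(round(w))), step = max(1L, as.integer(round(s))))
}

#' Equal-width grasp-force level scheme
#'
#' Grip force is evenly divided into `n_levels` bins between `force_min`
#' and `force_max` (defaults: 8 bins over 0-40 N, i.e. 5 N per level).
#'
#' @param n_levels number of levels.
#' @param force_min,force_max force span (N).
#' @return an object of class `level_scheme`.
#' @export
level_scheme <- function(n_levels = 8, force_min = 0, force_max = 40) {
  if (n_levels < 2) stop_validation("n_levels must be >= 2")
  if (force_max <= force_min) stop_validation("force_max must exceed force_min")
  structure(list(n_levels = as.integer(n_levels),
                 force_min = as.numeric(force_min),
                 force_max = as.numeric(force_max)),
            class = "level_scheme")
}

bin_width <- function(scheme) (scheme$force_max - scheme$force_min) / scheme$n_levels

#' Midpoint force of a level's bin
#' @param level level index (vectorized).
#' @param scheme a [level_scheme()].
#' @return bin midpoint(s) in newtons.
#' @export
level_midpoint <- function(level, scheme = level_scheme()) {
  scheme$force_min + (level - 0.5) * bin_width(scheme)
}

#' Quantize a force value to its level index
#'
#' Bins are half-open `[lo, hi)`; the top bin is closed so
#' `force_max` maps to level `n_levels`.
#'
#' @param f force value(s) in newtons, within the scheme's range.
#' @param scheme a [level_scheme()].
#' @return integer level index/indices.
#' @export
quantize_force <- function(f, scheme = level_scheme()) {
  if (any(f < scheme$force_min | f > scheme$force_max))
    stop("force value out of range [", scheme$force_min, ", ",
         scheme$force_max, "] N: ",
         f[which(f < scheme$force_min | f > scheme$force_max)[1]])
  lv <- floor((f - scheme$force_min) / bin_width(scheme)) + 1
  as.integer(pmin(lv, scheme$n_levels))
}

#' Mean-force feature of a force window
#' @param window non-empty numeric vector of force samples (N).
#' @return arithmetic mean (N).
#' @export
force_feature <- function(window) {
  if (length(window) < 1L) stop_validation("empty force window")
  mean(window)
}

# Start indices (0-based) of all full windows of a segment of length `len`.
window_starts <- function(len, w, s) {
  if (len < w) return(integer(0))
  seq.int(0L, len - w, by = s)
}

#' Cut overlapping windows out of a segment
#'
#' Windows of length W samples every S samples, anchored at the segment
#' start; a trailing partial window is discarded, so the count is
#' `floor((len - W)/S) + 1` for `len >= W` and 0 otherwise.
#'
#' @param rec a [session_recording()].
#' @param spec a [window_spec()].
#' @param segment integer length-2, 0-based half-open `[start, end)` sample
#'   interval (defaults to the whole recording).
#' @return list of windows; each has `emg` (channels x W), `force`
#'   (length W) and `start` (0-based sample index into the recording).
#' @export
slice_windows <- function(rec, spec = window_spec(),
                          segment = c(0L, n_samples(rec))) {
  stopifnot(inherits(rec, "session_recording"))
  if (segment[1] < 0 || segment[2] > n_samples(rec) || segment[1] >= segment[2])
    stop_validation("invalid segment [", segment[1], ", ", segment[2], ")")
  ws <- window_samples(spec, rec$sampling_rate)
  starts <- window_starts(segment[2] - segment[1], ws["window"], ws["step"])
  lapply(starts, function(st) {
    a <- segment[1] + st
    idx <- (a + 1):(a + ws["window"])           # 1-based column indices
    list(emg = rec$emg[, idx, drop = FALSE], force = rec$force[idx],
         start = a)
  })
}

#' Default onset threshold from a calibration rest period
#'
#' The activity detector compares the summed per-window MAV of all
#' channels against a preset threshold. The default is 3 x the summed MAV
#' of a known rest stretch (scale-free across subjects and gains).
#'
#' @param rec a [session_recording()].
#' @param spec a [window_spec()].
#' @param rest_interval 0-based half-open sample interval known to be rest;
#'   defaults to the first 0.5 s of the recording.
#' @param multiplier threshold = multiplier x median rest summed MAV.
#' @return threshold in signal units.
#' @export
default_onset_threshold <- function(rec, spec = window_spec(),
                                    rest_interval = NULL, multiplier = 3) {
  if (is.null(rest_interval))
    rest_interval <- c(0L, min(n_samples(rec),
                               as.integer(round(0.5 * rec$sampling_rate))))
  wins <- slice_windows(rec, spec, rest_interval)
  if (length(wins) == 0L)
    stop_validation("rest interval shorter than one window")
  smav <- vapply(wins, function(w) sum(rowMeans(abs(w$emg))), numeric(1))
  multiplier * stats::median(smav)
}

#' Detect activity segments from summed-MAV windows
#'
#' Per window, the MAVs of all channels are summed and compared with the
#' threshold: a segment opens at the first window at or above threshold
#' and closes before the first subsequent window below it. Segments are
#' returned as maximal non-overlapping 0-based half-open sample intervals
#' (from the opening window's first sample to the last supra-threshold
#' window's end).
#'
#' @param rec a [session_recording()].
#' @param spec a [window_spec()].
#' @param threshold summed-MAV threshold (> 0, signal units); see
#'   [default_onset_threshold()].
#' @return list of integer length-2 vectors `c(start, end)`; empty if the
#'   recording is shorter than one window or nothing crosses threshold.
#' @export
detect_activity <- function(rec, spec = window_spec(), threshold) {
  stopifnot(inherits(rec, "session_recording"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop_validation("threshold must be a positive scalar")
  ws <- window_samples(spec, rec$sampling_rate)
  if (n_samples(rec) < ws["window"]) return(list())
  starts <- window_starts(n_samples(rec), ws["window"], ws["step"])
  active <- vapply(starts, function(a) {
    idx <- (a + 1):(a + ws["window"])
    sum(rowMeans(abs(rec$emg[, idx, drop = FALSE]))) >= threshold
  }, logical(1))
  segments <- list()
  i <- 1L
  while (i <= length(active)) {
    if (active[i]) {
      j <- i
      while (j < length(active) && active[j + 1L]) j <- j + 1L
      segments[[length(segments) + 1L]] <-
        c(starts[i], starts[j] + ws[["window"]])
      i <- j + 1L
    } else i <- i + 1L
  }
  segments
}
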