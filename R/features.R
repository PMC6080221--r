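# Time-domain window features and feature-table assembly.
# Feature order is fixed (MAV, RMS, SD, WL) and the layout is
# channel-major (all features of channel 1, then channel 2, ...):
# PCA and network weights depend on column identity.

FEATURE_ORDER <- c("MAV", "RMS", "SD", "WL")

#' Mean absolute value of a window
#' @param x numeric window samples (length >= 1).
#' @return `mean(|x|)` (signal units).
#' @export
emg_mav <- function(x) {
  if (length(x) < 1L) stop_validation("MAV needs a non-empty window")
  mean(abs(x))
}

#' Root mean square of a window
#' @param x numeric window samples (length >= 1).
#' @return `sqrt(mean(x^2))` (signal units).
#' @export
emg_rms <- function(x) {
  if (length(x) < 1L) stop_validation("RMS needs a non-empty window")
  sqrt(mean(x^2))
}

#' Sample standard deviation of a window
#' @param x numeric window samples (length >= 2; denominator N - 1).
#' @return `sqrt(sum((x - mean(x))^2) / (N - 1))` (signal units).
#' @export
emg_sd <- function(x) {
  if (length(x) < 2L) stop_validation("SD needs at least 2 samples")
  sqrt(sum((x - mean(x))^2) / (length(x) - 1))
}

#' Waveform length of a window
#' @param x numeric window samples (length >= 2).
#' @return `sum(|x[i+1] - x[i]|)` (signal units).
#' @export
emg_wl <- function(x) {
  if (length(x) < 2L) stop_validation("WL needs at least 2 samples")
  sum(abs(diff(x)))
}

feature_fun <- list(MAV = emg_mav, RMS = emg_rms, SD = emg_sd, WL = emg_wl)

# Feature vector of one multi-channel window: channel-major, feature order
# as in `features`.
window_features <- function(emg, features) {
  out <- numeric(nrow(emg) * length(features))
  k <- 0L
  for (c in seq_len(nrow(emg))) {
    for (f in features) {
      k <- k + 1L
      out[k] <- feature_fun[[f]](emg[c, ])
    }
  }
  out
}

#' Build the per-window feature table of a session
#'
#' Detects activity (unless segments are given), cuts overlapping windows
#' anchored at each segment start, and emits one row per window: the
#' selected time-domain features of the selected channels
#' (channel-major), the mean-force feature of the synchronized force
#' window, and its quantized level label.
#'
#' @param rec a [session_recording()].
#' @param spec a [window_spec()].
#' @param scheme a [level_scheme()].
#' @param features subset of `c("MAV", "RMS", "SD", "WL")` (order fixed).
#' @param channels channel indices to use (default: all).
#' @param segments list of 0-based half-open sample intervals; `NULL`
#'   (default) runs [detect_activity()] with `threshold`.
#' @param threshold onset threshold; `NULL` (default) calibrates it from
#'   the first 0.5 s of the recording via [default_onset_threshold()].
#' @param trim_windows windows dropped at each end of every segment
#'   (default 1), discarding onset/release transients.
#' @return an object of class `feature_table`: list with `features`
#'   (rows x columns matrix, named columns `ch<k>_<FEAT>`), `force` (N per
#'   row), `level` (label per row), `subject_id`, and bookkeeping fields.
#' @export
build_feature_table <- function(rec, spec = window_spec(),
                                scheme = level_scheme(),
                                features = FEATURE_ORDER,
                                channels = NULL,
                                segments = NULL, threshold = NULL,
                                trim_windows = 1L) {
  stopifnot(inherits(rec, "session_recording"))
  features <- FEATURE_ORDER[FEATURE_ORDER %in% features]
  if (length(features) == 0L)
    stop_validation("features must be a non-empty subset of MAV/RMS/SD/WL")
  channels <- channels %||% seq_len(n_channels(rec))
  if (length(channels) == 0L || any(channels < 1 | channels > n_channels(rec)))
    stop_validation("invalid channel selection")
  if (is.null(segments)) {
    if (is.null(threshold)) threshold <- default_onset_threshold(rec, spec)
    segments <- detect_activity(rec, spec, threshold)
  }
  ws <- window_samples(spec, rec$sampling_rate)
  rows <- list(); force <- numeric(0); start <- integer(0)
  for (seg in segments) {
    wins <- slice_windows(rec, spec, seg)
    if (trim_windows > 0L && length(wins) > 2L * trim_windows)
      wins <- wins[(trim_windows + 1L):(length(wins) - trim_windows)]
    else if (trim_windows > 0L && length(wins) <= 2L * trim_windows)
      next
    for (w in wins) {
      rows[[length(rows) + 1L]] <-
        window_features(w$emg[channels, , drop = FALSE], features)
      force <- c(force, force_feature(w$force))
      start <- c(start, w$start)
    }
  }
  x <- if (length(rows)) do.call(rbind, rows)
       else matrix(numeric(0), 0, length(channels) * length(features))
  colnames(x) <- as.vector(t(outer(channels, features,
                                   function(c, f) paste0("ch", c, "_", f))))
  keep <- force >= scheme$force_min & force <= scheme$force_max
  structure(list(features = x[keep, , drop = FALSE],
                 force = force[keep],
                 level = if (any(keep)) quantize_force(force[keep], scheme)
                         else integer(0),
                 window_start = start[keep],
                 subject_id = rec$subject_id,
                 feature_names = features,
                 channels = channels,
                 scheme = scheme),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d windows x %d features (%s; channels %s)\n",
              nrow(x$features), ncol(x$features),
              paste(x$feature_names, collapse = "+"),
              paste(x$channels, collapse = ",")))
  invisible(x)
}

#' Stack feature tables from several sessions of one subject
#' @param tables list of `feature_table` objects with identical layout.
#' @return a single `feature_table`.
#' @export
bind_feature_tables <- function(tables) {
  stopifnot(length(tables) >= 1L)
  ref <- tables[[1L]]
  for (t in tables[-1L])
    if (!identical(colnames(t$features), colnames(ref$features)))
      stop_validation("feature tables have different layouts")
  structure(list(features = do.call(rbind, lapply(tables, `[[`, "features")),
                 force = unlist(lapply(tables, `[[`, "force")),
                 level = unlist(lapply(tables, `[[`, "level")),
                 window_start = unlist(lapply(tables, `[[`, "window_start")),
                 subject_id = ref$subject_id,
                 feature_names = ref$feature_names,
                 channels = ref$channels,
                 scheme = ref$scheme),
            class = "feature_table")
}

#' Feature table as a data frame (and CSV-ready layout)
#' @param x a `feature_table`.
#' @param ... unused.
#' @return data frame with feature columns plus `force_N` and `level`.
#' @export
as.data.frame.feature_table <- function(x, ...) {
  cbind(as.data.frame(x$features), force_N = x$force, level = x$level)
}

#' Write a feature table as CSV
#' @param table a `feature_table`.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
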