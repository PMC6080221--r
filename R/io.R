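# Session and model I/O: plain CSV + JSON sidecar for recordings, a JSON
# container for trained model bundles. All files are UTF-8 text so fixtures
# stay diffable.

IO_SCHEMA_VERSION <- "1.0"

#' Construct a synchronized sEMG/force recording
#'
#' @param emg numeric matrix, channels x samples (armband amplitude units).
#' @param force numeric vector of grip force samples (newtons); must have
#'   as many samples as `emg` has columns.
#' @param sampling_rate sampling rate in Hz (both traces share it).
#' @param subject_id subject identifier.
#' @param level_label optional force-level index the session was acquired at.
#' @param metadata free-form named list (units, ground-truth annotations...).
#' @return an object of class `session_recording`.
#' @export
session_recording <- function(emg, force, sampling_rate,
                              subject_id = "anonymous", level_label = NULL,
                              metadata = list()) {
  emg <- as.matrix(emg)
  force <- as.numeric(force)
  if (!is.numeric(emg)) stop_validation("emg must be numeric")
  if (nrow(emg) < 1L) stop_validation("need at least one sEMG channel")
  if (ncol(emg) != length(force))
    stop_validation("emg has ", ncol(emg), " samples but force has ",
                    length(force))
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0)
    stop_validation("sampling_rate must be a positive scalar")
  if (anyNA(force)) stop_validation("force trace contains NA")
  structure(list(emg = emg, force = force,
                 sampling_rate = as.numeric(sampling_rate),
                 subject_id = as.character(subject_id),
                 level_label = if (is.null(level_label)) NULL
                               else as.integer(level_label),
                 metadata = metadata),
            class = "session_recording")
}

#' @export
print.session_recording <- function(x, ...) {
  cat(sprintf("<session_recording> subject %s, %d ch x %d samples @ %g Hz",
              x$subject_id, nrow(x$emg), ncol(x$emg), x$sampling_rate))
  if (!is.null(x$level_label)) cat(", level", x$level_label)
  cat("\n")
  invisible(x)
}

n_samples <- function(rec) ncol(rec$emg)
n_channels <- function(rec) nrow(rec$emg)

#' Write a recording as CSV plus JSON sidecar
#'
#' The CSV has one row per sample with columns `time_s`, `emg_1..emg_C`,
#' `force_N` (time derived as 0-based index / sampling rate). The sidecar
#' `<path>.json` carries sampling rate, subject, level and declared shape.
#'
#' @param rec a [session_recording()].
#' @param path path of the CSV file to create (sidecar gets `.json` added).
#' @return invisibly, the paths written.
#' @export
write_session <- function(rec, path) {
  stopifnot(inherits(rec, "session_recording"))
  C <- n_channels(rec); S <- n_samples(rec)
  df <- data.frame(time_s = (seq_len(S) - 1) / rec$sampling_rate,
                   t(rec$emg), force_N = rec$force)
  names(df) <- c("time_s", paste0("emg_", seq_len(C)), "force_N")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  sidecar <- paste0(path, ".json")
  meta <- list(schema_version = IO_SCHEMA_VERSION,
               sampling_rate = rec$sampling_rate,
               subject_id = rec$subject_id,
               level_label = rec$level_label,
               n_channels = C, n_samples = S,
               metadata = rec$metadata)
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(c(csv = path, sidecar = sidecar))
}

#' Read a recording written by [write_session()]
#'
#' Declared and actual shapes must agree; mismatches and non-finite force
#' values raise a parse error naming the offending row/column.
#'
#' @param path path of the CSV file (its `.json` sidecar must exist).
#' @return a [session_recording()].
#' @export
read_session <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(path)) stop_parse("no such session file: ", path)
  if (!file.exists(sidecar)) stop_parse("missing sidecar: ", sidecar)
  meta <- tryCatch(jsonlite::read_json(sidecar, simplifyVector = TRUE),
                   error = function(e) stop_parse("unreadable sidecar: ",
                                                  conditionMessage(e)))
  for (f in c("schema_version", "sampling_rate", "n_channels", "n_samples"))
    if (is.null(meta[[f]])) stop_parse("sidecar lacks field '", f, "'")
  if (!identical(as.character(meta$schema_version), IO_SCHEMA_VERSION))
    stop_parse("unsupported session schema_version: ", meta$schema_version)
  df <- utils::read.csv(path)
  C <- as.integer(meta$n_channels)
  want <- c("time_s", paste0("emg_", seq_len(C)), "force_N")
  if (!identical(names(df), want))
    stop_parse("CSV columns (", paste(names(df), collapse = ","),
               ") do not match the ", C, "-channel schema")
  if (nrow(df) != meta$n_samples)
    stop_parse("CSV has ", nrow(df), " rows, sidecar declares ",
               meta$n_samples)
  bad <- which(!is.finite(df$force_N))
  if (length(bad))
    stop_parse("non-finite force_N at row ", bad[1])
  session_recording(emg = t(as.matrix(df[paste0("emg_", seq_len(C))])),
                    force = df$force_N,
                    sampling_rate = meta$sampling_rate,
                    subject_id = meta$subject_id %||% "anonymous",
                    level_label = meta$level_label,
                    metadata = as.list(meta$metadata %||% list()))
}

#' Write a cohort of recordings with a manifest
#'
#' Writes each session via [write_session()] under `dir` and a
#' `manifest.json` listing subject, level, file, sampling rate and shape.
#'
#' @param sessions list of [session_recording()] objects.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
write_session_set <- function(sessions, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- vector("list", length(sessions))
  for (i in seq_along(sessions)) {
    rec <- sessions[[i]]
    fname <- sprintf("%s_L%s_%03d.csv", rec$subject_id,
                     rec$level_label %||% 0L, i)
    write_session(rec, file.path(dir, fname))
    entries[[i]] <- list(subject_id = rec$subject_id,
                         level_label = rec$level_label,
                         file = fname,
                         sampling_rate = rec$sampling_rate,
                         n_samples = n_samples(rec),
                         n_channels = n_channels(rec))
  }
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(schema_version = IO_SCHEMA_VERSION,
                            sessions = entries),
                       manifest, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(manifest)
}

#' Read a cohort written by [write_session_set()]
#' @param dir directory holding `manifest.json` and session files.
#' @return list of [session_recording()] objects.
#' @export
read_session_set <- function(dir) {
  manifest <- file.path(dir, "manifest.json")
  if (!file.exists(manifest)) stop_parse("missing manifest: ", manifest)
  m <- jsonlite::read_json(manifest, simplifyVector = FALSE)
  lapply(m$sessions, function(e) {
    rec <- read_session(file.path(dir, e$file))
    if (n_samples(rec) != e$n_samples || n_channels(rec) != e$n_channels)
      stop_parse("manifest/file shape mismatch for ", e$file)
    rec
  })
}

# ---- model bundles ---------------------------------------------------------

# Recursively convert a model object (nested lists of numeric vectors /
# matrices / character scalars) to a JSON-ready form that preserves matrix
# shape, and back.
pack_numeric <- function(x) {
  if (is.matrix(x)) list(`_matrix` = dim(x), data = as.numeric(x))
  else if (is.numeric(x) || is.character(x) || is.logical(x) || is.null(x)) x
  else if (is.list(x)) {
    cls <- attr(x, "class")
    body <- lapply(unclass(x), pack_numeric)
    if (is.null(cls)) body else list(`_class` = cls, data = body)
  }
  else stop_validation("cannot serialize component of class ",
                       paste(class(x), collapse = "/"))
}

unpack_numeric <- function(x) {
  if (is.list(x) && !is.null(x$`_matrix`))
    matrix(as.numeric(unlist(x$data)), nrow = x$`_matrix`[[1]],
           ncol = x$`_matrix`[[2]])
  else if (is.list(x) && !is.null(x$`_class`))
    structure(lapply(x$data, unpack_numeric),
              class = as.character(unlist(x$`_class`)))
  else if (is.list(x)) {
    # jsonlite reads unboxed vectors as lists of scalars; coerce back
    if (length(x) > 0 && is.null(names(x)) &&
        all(vapply(x, function(e) is.atomic(e) && length(e) == 1L &&
                                  !is.null(e), logical(1))))
      unlist(x)
    else lapply(x, unpack_numeric)
  }
  else x
}

#' Save a trained model bundle as JSON
#'
#' Handles [fit_pca()] models, [train_force_predictor()] bundles and single
#' autoencoder models. Numbers are written at full precision so reloaded
#' models predict bit-identically.
#'
#' @param model the model object.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
save_model <- function(model, path) {
  payload <- list(schema_version = IO_SCHEMA_VERSION,
                  model_class = class(model)[1],
                  body = pack_numeric(unclass(model)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' Load a model bundle written by [save_model()]
#' @param path file written by [save_model()].
#' @return the model object with its class restored.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop_parse("no such model file: ", path)
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                      error = function(e) stop_parse("unreadable model file: ",
                                                     conditionMessage(e)))
  if (is.null(payload$schema_version) || is.null(payload$model_class))
    stop_parse("not a model bundle: ", path)
  if (!identical(as.character(payload$schema_version), IO_SCHEMA_VERSION))
    stop_parse("unsupported model schema_version: ", payload$schema_version)
  structure(unpack_numeric(payload$body), class = payload$model_class)
}
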