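#' Construct a raw multichannel EEG recording
#'
#' The package's basic container: a channels x samples numeric matrix with a
#' sampling rate and one montage label per channel. Sample indices are
#' 0-based in all windowing arithmetic and windows are half-open
#' `[start, stop)`.
#'
#' @param data numeric matrix, `C` channels x `M` samples.
#' @param rate sampling rate in samples per second (`R > 0`).
#' @param channel_names character vector of `C` unique montage labels
#'   (10-20 system, e.g. `"Fp1"`). Defaults to `ch01, ch02, ...`.
#' @param subject_id,trial_id opaque identifiers carried through the
#'   pipeline (used by subject-wise cross-validation splits).
#' @return an object of class `raw_recording`.
#' @examples
#' rec <- raw_recording(matrix(rnorm(4 * 256), 4, 256), rate = 128)
#' n_channels(rec); n_samples(rec); duration(rec)
#' @export
raw_recording <- function(data, rate, channel_names = NULL,
                          subject_id = NA_character_,
                          trial_id = NA_character_) {
  if (!is.matrix(data) || !is.numeric(data))
    abort("`data` is not a channels x samples numeric matrix")
  C <- nrow(data); M <- ncol(data)
  if (C < 2L) abort("not a channels x samples matrix: need at least 2 channels, got %d", C)
  if (M < 1L) abort("recording has no samples")
  if (!is_scalar_num(rate) || rate <= 0) abort("`rate` must be a positive number")
  if (is.null(channel_names)) channel_names <- sprintf("ch%02d", seq_len(C))
  channel_names <- as.character(channel_names)
  if (length(channel_names) != C)
    abort("channel name count (%d) does not match channel count (%d)",
          length(channel_names), C)
  if (anyDuplicated(channel_names)) abort("channel names must be unique")
  rownames(data) <- channel_names
  structure(
    list(data = data, rate = as.numeric(rate), channel_names = channel_names,
         subject_id = as.character(subject_id), trial_id = as.character(trial_id)),
    class = "raw_recording")
}

#' @rdname raw_recording
#' @param rec a `raw_recording`.
#' @export
n_channels <- function(rec) nrow(rec$data)

#' @rdname raw_recording
#' @export
n_samples <- function(rec) ncol(rec$data)

#' @rdname raw_recording
#' @export
duration <- function(rec) ncol(rec$data) / rec$rate

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d channels x %d samples @ %g Hz (%.2f s)\n",
              n_channels(x), n_samples(x), x$rate, duration(x)))
  cat(sprintf("  subject: %s  trial: %s\n", x$subject_id, x$trial_id))
  invisible(x)
}

#' Drop the pre-stimulus portion of a recording
#'
#' Emotional responses to a stimulus build up over time, so the first part of
#' each trial is routinely discarded (30 s for long film-clip trials).
#' Removes the first `round(skip_seconds * rate)` samples.
#'
#' @param rec a [raw_recording()].
#' @param skip_seconds non-negative seconds to discard from the start.
#' @return a `raw_recording` with the leading samples removed; metadata
#'   preserved.
#' @export
trim_prestimulus <- function(rec, skip_seconds) {
  stopifnot(inherits(rec, "raw_recording"))
  if (!is_scalar_num(skip_seconds) || skip_seconds < 0)
    abort("`skip_seconds` must be a non-negative number")
  n_skip <- round(skip_seconds * rec$rate)
  M <- n_samples(rec)
  if (n_skip >= M)
    abort("cannot skip %g s (%d samples): recording has only %d samples",
          skip_seconds, n_skip, M)
  if (n_skip == 0) return(rec)
  raw_recording(rec$data[, (n_skip + 1L):M, drop = FALSE], rec$rate,
                rec$channel_names, rec$subject_id, rec$trial_id)
}

#' Save / load a recording as a plain-text matrix plus JSON sidecar
#'
#' Recordings are stored as a delimited text matrix (channels x samples, no
#' header) next to a `<stem>.json` sidecar holding the sampling rate, channel
#' names, identifiers and, optionally, the trial label. `format = "rds"` is
#' available for exact binary round-trips of run-time intermediates.
#'
#' @param rec a [raw_recording()].
#' @param dir output directory (created if missing).
#' @param stem file stem; defaults to `<subject>_<trial>`.
#' @param format one of `"csv"`, `"tsv"`, `"rds"`.
#' @param label optional [emotion_label()] written into the sidecar.
#' @return (invisibly) the path of the data file.
#' @export
save_recording <- function(rec, dir, stem = NULL,
                           format = c("csv", "tsv", "rds"), label = NULL) {
  stopifnot(inherits(rec, "raw_recording"))
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(stem)) stem <- paste0(rec$subject_id, "_", rec$trial_id)
  data_path <- file.path(dir, paste0(stem, ".", format))
  if (format == "rds") {
    saveRDS(rec$data, data_path)
  } else {
    sep <- if (format == "csv") "," else "\t"
    data.table::fwrite(data.table::as.data.table(rec$data), data_path,
                       sep = sep, col.names = FALSE)
  }
  sidecar <- list(rate = rec$rate, channel_names = rec$channel_names,
                  subject_id = rec$subject_id, trial_id = rec$trial_id,
                  n_channels = n_channels(rec), n_samples = n_samples(rec),
                  orientation = "channels_x_samples")
  if (!is.null(label)) {
    stopifnot(inherits(label, "emotion_label"))
    sidecar$label <- list(scheme = label$scheme, value = label$value,
                          class_names = label$class_names)
  }
  jsonlite::write_json(sidecar, file.path(dir, paste0(stem, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(data_path)
}

#' @rdname save_recording
#' @param path data file path (`.csv`, `.tsv` or `.rds`); a `<stem>.json`
#'   sidecar next to it is read when present.
#' @param rate,channel_names,subject_id,trial_id metadata overrides used when
#'   no sidecar exists.
#' @return `load_recording()` returns a `raw_recording`. If the stored array
#'   is samples x channels and `channel_names` disambiguates the orientation,
#'   it is transposed.
#' @export
load_recording <- function(path, format = NULL, rate = NULL,
                           channel_names = NULL, subject_id = NULL,
                           trial_id = NULL) {
  if (!file.exists(path)) abort("file not found: %s", path)
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  if (!format %in% c("csv", "tsv", "rds")) abort("unsupported format: %s", format)
  sidecar_path <- paste0(tools::file_path_sans_ext(path), ".json")
  meta <- list()
  if (file.exists(sidecar_path)) meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  rate <- rate %||% meta$rate
  channel_names <- channel_names %||% meta$channel_names
  subject_id <- subject_id %||% meta$subject_id %||% NA_character_
  trial_id <- trial_id %||% meta$trial_id %||% NA_character_
  if (is.null(rate)) abort("sampling rate not given and no sidecar found for %s", path)

  if (format == "rds") {
    data <- readRDS(path)
  } else {
    dt <- data.table::fread(path, header = FALSE,
                            sep = if (format == "csv") "," else "\t")
    data <- as.matrix(dt)
  }
  if (is.null(dim(data)) || length(dim(data)) != 2L || min(dim(data)) < 2L)
    abort("not a channels x samples matrix (got %s)",
          paste(dim(data) %||% length(data), collapse = " x "))
  # orient: channel_names length decides which axis is channels
  if (!is.null(channel_names)) {
    Cn <- length(channel_names)
    if (nrow(data) != Cn && ncol(data) == Cn) data <- t(data)
    if (nrow(data) != Cn)
      abort("channel-count mismatch: %d names but array is %d x %d",
            Cn, nrow(data), ncol(data))
  }
  dimnames(data) <- NULL
  raw_recording(data, rate, channel_names, subject_id, trial_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Standard montage label sets
#'
#' Channel orderings matching the two common affective-EEG acquisition
#' layouts: the 32-electrode, 128 Hz layout used with valence/arousal
#' self-ratings and the 62-electrode, 200 Hz layout used with categorical
#' positive/neutral/negative labels.
#'
#' @return character vector of 10-20-system channel labels.
#' @export
montage_32 <- function() c(
  "Fp1", "AF3", "F3", "F7", "FC5", "FC1", "C3", "T7", "CP5", "CP1", "P3",
  "P7", "PO3", "O1", "Oz", "Pz", "Fp2", "AF4", "Fz", "F4", "F8", "FC6",
  "FC2", "Cz", "C4", "T8", "CP6", "CP2", "P4", "P8", "PO4", "O2")

#' @rdname montage_32
#' @export
montage_62 <- function() c(
  "Fp1", "Fpz", "Fp2", "AF3", "AF4", "F7", "F5", "F3", "F1", "Fz", "F2",
  "F4", "F6", "F8", "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6",
  "FT8", "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8", "TP7", "CP5",
  "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8", "P7", "P5", "P3", "P1",
  "Pz", "P2", "P4", "P6", "P8", "PO7", "PO5", "PO3", "POz", "PO4", "PO6",
  "PO8", "CB1", "O1", "Oz", "O2", "CB2")
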