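#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom tidyr pivot_longer pivot_wider
#' @importFrom purrr map map_dbl map2 imap
NULL

#' Standard montages
#'
#' The 16-channel motor-cortex EEG montage (international 10-20 labels) and the
#' 10-muscle upper-limb surface EMG montage used throughout the package.
#'
#' @format Character vectors of channel labels.
#' @name montages
#' @export
eeg_montage_16 <- c(
  "P4", "CP2", "FC5", "C3", "P3", "C2", "FC6", "C4",
  "CP6", "F3", "FC2", "FC1", "F4", "CP5", "C1", "CP1"
)

#' @rdname montages
#' @export
emg_muscles_10 <- c(
  "FDS", "FCU", "FCR", "ECU", "ECRL", "BB", "TB", "DM", "DA", "DP"
)

#' Multichannel recording container
#'
#' A `recording` holds one subject's multichannel time series (EEG or EMG) as a
#' channels x samples matrix in microvolts, together with the sampling rate and
#' unique channel labels.
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param fs Sampling rate in Hz (> 0).
#' @param channel_labels Character vector of unique channel names, one per row
#'   of `data`. Defaults to `rownames(data)`.
#' @param modality `"EEG"` or `"EMG"`.
#' @return An object of class `recording`.
#' @export
#' @examples
#' rec <- recording(matrix(rnorm(32), nrow = 2), fs = 500,
#'                  channel_labels = c("C3", "C4"), modality = "EEG")
#' rec
recording <- function(data, fs, channel_labels = rownames(data),
                      modality = c("EEG", "EMG")) {
  modality <- match.arg(modality)
  if (!is.matrix(data) || !is.numeric(data)) {
    abort("`data` must be a numeric channels x samples matrix.")
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    abort("`fs` must be a single positive number (Hz).")
  }
  if (is.null(channel_labels)) {
    channel_labels <- paste0("ch", seq_len(nrow(data)))
  }
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(data)) {
    abort("`channel_labels` must have one entry per channel (matrix row).")
  }
  if (anyDuplicated(channel_labels)) {
    abort("`channel_labels` must be unique.")
  }
  rownames(data) <- channel_labels
  structure(
    list(data = data, fs = as.numeric(fs), channel_labels = channel_labels,
         modality = modality),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %s: %d channels x %d samples @ %g Hz (%.2f s)\n",
              x$modality, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs))
  cat("channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as_tibble.recording <- function(x, ...) {
  tibble(
    channel = rep(x$channel_labels, times = ncol(x$data)),
    time_s = rep((seq_len(ncol(x$data)) - 1) / x$fs, each = nrow(x$data)),
    value_uV = as.vector(x$data)
  )
}

n_samples <- function(rec) ncol(rec$data)
n_channels <- function(rec) nrow(rec$data)

#' Read and write recordings as CSV with a JSON sidecar
#'
#' Recordings are stored as plain CSV, samples as rows and channels as columns
#' with a header row of channel labels, in microvolts. A JSON sidecar
#' (`<path>.json`) carries the sampling rate, channel order and modality so a
#' round trip preserves the object. EDF input is not supported by this build;
#' convert to CSV upstream.
#'
#' @param path CSV file path.
#' @param rec A [recording()].
#' @param format Input format; only `"csv"` is implemented.
#' @param fs,modality Used when no JSON sidecar is found next to `path`.
#' @return `read_recording()` returns a [recording()]; `write_recording()`
#'   returns `path` invisibly.
#' @export
read_recording <- function(path, format = c("csv", "edf"), fs = NULL,
                           modality = NULL) {
  format <- match.arg(format)
  if (format == "edf") {
    abort("EDF input is not supported by this build; export the recording to CSV.")
  }
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  sidecar <- paste0(path, ".json")
  meta <- NULL
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  fs <- fs %||% meta$fs
  modality <- modality %||% meta$modality %||% "EEG"
  if (is.null(fs)) {
    abort("`fs` missing: supply it or provide the JSON sidecar written by write_recording().")
  }
  df <- tryCatch(
    utils::read.csv(path, check.names = FALSE),
    error = function(e) abort(sprintf("Failed to parse CSV '%s': %s", path,
                                      conditionMessage(e)))
  )
  if (ncol(df) < 1L || nrow(df) < 1L) {
    abort(sprintf("CSV '%s' has no data (field: data matrix).", path))
  }
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    abort(sprintf("CSV '%s' contains non-numeric sample values (field: data matrix).", path))
  }
  if (!is.null(meta$channel_labels) &&
      !identical(colnames(df), as.character(meta$channel_labels))) {
    abort(sprintf("CSV '%s': header labels do not match sidecar channel_labels.", path))
  }
  recording(t(m), fs = fs, channel_labels = colnames(df),
            modality = if (toupper(modality) == "EMG") "EMG" else "EEG")
}

#' @rdname read_recording
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  df <- as.data.frame(t(rec$data))
  colnames(df) <- rec$channel_labels
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(fs = rec$fs, channel_labels = rec$channel_labels,
         modality = rec$modality, n_samples = n_samples(rec)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
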