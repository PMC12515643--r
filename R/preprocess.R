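# Signal conditioning: zero-phase FIR filtering, resampling, re-referencing,
# epoching and amplitude-based artifact screening.

# Mirror (reflection) index into 1..n without repeating the edge sample,
# so short signals can still be padded by long filter half-lengths.
.mirror_idx <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * (n - 1L)
  k <- (i - 1L) %% p
  k <- ifelse(k >= n, p - k, k)
  k + 1L
}

# Apply a linear-phase FIR (odd length, even order) with zero net phase:
# reflect-pad by the group delay on both sides, filter by FFT overlap-add,
# and re-align by the group delay.
.fir_zerophase <- function(x, b) {
  n <- length(b) - 1L
  stopifnot(n %% 2L == 0L)
  d <- n %/% 2L
  N <- length(x)
  left <- x[.mirror_idx(seq.int(1L - d, 0L), N)]
  right <- x[.mirror_idx(seq.int(N + 1L, N + d), N)]
  xp <- c(left, x, right)
  y <- as.numeric(signal::fftfilt(b, c(xp, numeric(n))))
  y[seq.int(2L * d + 1L, length.out = N)]
}

# Hamming-window FIR order for a given transition bandwidth (Hz), forced even.
.fir_order <- function(fs, transition) {
  n <- ceiling(3.3 * fs / transition)
  n + (n %% 2L)
}

.apply_fir <- function(rec, b) {
  out <- rec
  out$data <- t(apply(rec$data, 1L, .fir_zerophase, b = b))
  rownames(out$data) <- rec$channel_labels
  out
}

#' Zero-phase FIR band-pass filter
#'
#' Filters every channel with a Hamming-window linear-phase FIR band-pass
#' applied at zero phase (reflection padding plus group-delay compensation),
#' so the passband gain is within 1% of unity and no temporal shift is
#' introduced. Defaults correspond to the usual resting-state EEG band;
#' use `low = 20, high = 400` for surface EMG.
#'
#' @param rec A [recording()].
#' @param low,high Band edges in Hz, `0 < low < high < fs/2`.
#' @return The filtered [recording()].
#' @export
bandpass_filter <- function(rec, low = 0.5, high = 45) {
  stopifnot(inherits(rec, "recording"))
  if (!(low > 0 && high > low)) abort("Require 0 < low < high.")
  if (high >= rec$fs / 2) {
    abort(sprintf("high = %g Hz is at or above Nyquist (%g Hz).", high, rec$fs / 2))
  }
  transition <- min(low, rec$fs / 2 - high)
  n <- .fir_order(rec$fs, transition)
  b <- signal::fir1(n, c(low, high) / (rec$fs / 2), type = "pass")
  .apply_fir(rec, b)
}

#' Zero-phase FIR notch (band-stop) filter
#'
#' Suppresses power-line interference with a narrow FIR band-stop centred on
#' `freq`. Attenuation at `freq` exceeds 20 dB while frequencies 5 Hz away
#' stay within 5% of unity gain.
#'
#' @param rec A [recording()].
#' @param freq Notch centre frequency in Hz, `0 < freq < fs/2`.
#' @param half_width Half width of the stop band in Hz.
#' @return The filtered [recording()].
#' @export
notch_filter <- function(rec, freq = 50, half_width = 2) {
  stopifnot(inherits(rec, "recording"))
  if (!(freq > 0 && freq < rec$fs / 2)) {
    abort(sprintf("Notch frequency must lie in (0, %g) Hz.", rec$fs / 2))
  }
  transition <- half_width
  n <- .fir_order(rec$fs, transition)
  edges <- c(freq - half_width, freq + half_width)
  if (edges[1] <= 0 || edges[2] >= rec$fs / 2) {
    abort("Notch band (freq +/- half_width) must lie strictly inside (0, Nyquist).")
  }
  b <- signal::fir1(n, edges / (rec$fs / 2), type = "stop")
  .apply_fir(rec, b)
}

#' Downsample a recording
#'
#' Anti-alias filters (zero-phase FIR low-pass with cutoff at 0.45 of the
#' target rate) and then evaluates the filtered signal on the new sampling
#' grid. The new sample count is `floor(n * target_fs / fs)`. Upsampling is
#' not supported.
#'
#' @param rec A [recording()].
#' @param target_fs New sampling rate in Hz, `<= fs`.
#' @return The resampled [recording()].
#' @export
resample_recording <- function(rec, target_fs = 500) {
  stopifnot(inherits(rec, "recording"))
  if (target_fs > rec$fs) abort("Upsampling is not supported (target_fs > fs).")
  if (target_fs <= 0) abort("`target_fs` must be positive.")
  if (target_fs == rec$fs) return(rec)
  cutoff <- 0.45 * target_fs
  n <- .fir_order(rec$fs, 0.1 * target_fs)
  b <- signal::fir1(n, cutoff / (rec$fs / 2), type = "low")
  N <- n_samples(rec)
  m <- floor(N * target_fs / rec$fs)
  t_old <- (seq_len(N) - 1) / rec$fs
  t_new <- (seq_len(m) - 1) / target_fs
  out <- rec
  out$data <- t(apply(rec$data, 1L, function(ch) {
    stats::approx(t_old, .fir_zerophase(ch, b), xout = t_new)$y
  }))
  rownames(out$data) <- rec$channel_labels
  out$fs <- target_fs
  out
}

#' Common average reference
#'
#' Re-references an EEG recording so that at every sample the mean across
#' channels is zero. Idempotent.
#'
#' @param rec An EEG [recording()] with at least two channels.
#' @return The re-referenced [recording()].
#' @export
common_average_reference <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  if (rec$modality != "EEG") abort("Common average reference applies to EEG recordings.")
  if (n_channels(rec) < 2L) abort("Need at least 2 channels to re-reference.")
  out <- rec
  out$data <- sweep(rec$data, 2L, colMeans(rec$data))
  out
}

#' Cut a recording into fixed-length epochs
#'
#' Splits the recording into consecutive non-overlapping windows of
#' `length_s` seconds; a trailing remainder shorter than one epoch is
#' dropped. A recording shorter than one epoch yields zero epochs with a
#' warning.
#'
#' @param rec A [recording()].
#' @param length_s Epoch length in seconds; `length_s * fs` must be a whole
#'   number of samples.
#' @return An object of class `epoch_set`: a list with `epochs`
#'   (epoch x channel x sample array), `fs`, `epoch_length_s`,
#'   `channel_labels`, `modality`, logical `kept` and `reject_reason`.
#' @export
epoch_recording <- function(rec, length_s = 2) {
  stopifnot(inherits(rec, "recording"))
  ns <- length_s * rec$fs
  if (abs(ns - round(ns)) > 1e-9) {
    abort("`length_s * fs` must be an integer number of samples.")
  }
  ns <- as.integer(round(ns))
  n_ep <- n_samples(rec) %/% ns
  if (n_ep == 0L) {
    warn(sprintf("Recording (%.3f s) is shorter than one %g-s epoch; returning 0 epochs.",
                 n_samples(rec) / rec$fs, length_s))
  }
  epochs <- array(0, dim = c(n_ep, n_channels(rec), ns))
  for (e in seq_len(n_ep)) {
    epochs[e, , ] <- rec$data[, seq.int((e - 1L) * ns + 1L, e * ns), drop = FALSE]
  }
  structure(
    list(epochs = epochs, fs = rec$fs, epoch_length_s = length_s,
         channel_labels = rec$channel_labels, modality = rec$modality,
         kept = rep(TRUE, n_ep), reject_reason = rep(NA_character_, n_ep)),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %s: %d epochs (%d kept) x %d channels x %d samples @ %g Hz\n",
              x$modality, dim(x$epochs)[1], sum(x$kept), dim(x$epochs)[2],
              dim(x$epochs)[3], x$fs))
  invisible(x)
}

n_kept <- function(ep) sum(ep$kept)

# epochs retained after screening, as a list of channel x sample matrices
kept_epoch_matrices <- function(ep) {
  idx <- which(ep$kept)
  lapply(idx, function(e) {
    m <- ep$epochs[e, , , drop = TRUE]
    m <- matrix(m, nrow = dim(ep$epochs)[2])
    rownames(m) <- ep$channel_labels
    m
  })
}

#' Amplitude-based epoch rejection
#'
#' Marks an epoch as rejected when any sample at any electrode exceeds the
#' threshold in absolute value (strictly `|v| > threshold_uV`); samples at
#' exactly the threshold are retained.
#'
#' @param ep An `epoch_set` from [epoch_recording()].
#' @param threshold_uV Rejection threshold in microvolts (default 80).
#' @return The `epoch_set` with `kept` and `reject_reason` updated.
#' @export
reject_amplitude <- function(ep, threshold_uV = 80) {
  stopifnot(inherits(ep, "epoch_set"))
  if (threshold_uV <= 0) abort("`threshold_uV` must be positive.")
  for (e in seq_len(dim(ep$epochs)[1])) {
    if (!ep$kept[e]) next
    peak <- max(abs(ep$epochs[e, , ]))
    if (peak > threshold_uV) {
      ep$kept[e] <- FALSE
      ep$reject_reason[e] <- sprintf("amplitude %.2f uV > %g uV", peak, threshold_uV)
    }
  }
  ep
}

#' Exclude epochs flagged by an external artifact screen
#'
#' Hook for upstream artifact identification (e.g. an ICA-based visual screen
#' performed outside this package): marks the listed epochs as rejected.
#'
#' @param ep An `epoch_set`.
#' @param indices Integer indices of epochs to exclude.
#' @param reason Free-text reason recorded in `reject_reason`.
#' @return The updated `epoch_set`.
#' @export
exclude_epochs <- function(ep, indices, reason = "external artifact screen") {
  stopifnot(inherits(ep, "epoch_set"))
  indices <- as.integer(indices)
  if (any(indices < 1L | indices > dim(ep$epochs)[1])) {
    abort("`indices` out of range.")
  }
  ep$kept[indices] <- FALSE
  ep$reject_reason[indices] <- reason
  ep
}

#' Standard EEG / EMG conditioning chains
#'
#' Convenience wrappers running the default conditioning sequence:
#' band-pass (EEG 0.5-45 Hz with 50 Hz notch; EMG 20-400 Hz), downsample to
#' 500 Hz, common average reference (EEG only), 2-s epochs, and +/- 80 uV
#' amplitude screening (EEG only).
#'
#' @param rec A [recording()].
#' @param band Band edges in Hz.
#' @param notch Notch frequency in Hz, or `NULL` to skip.
#' @param target_fs Resampling target in Hz, or `NULL` to skip.
#' @param epoch_length_s Epoch length in seconds.
#' @param reject_uV Amplitude screening threshold, or `NULL` to skip.
#' @param exclude Optional integer epoch indices excluded via [exclude_epochs()].
#' @return An `epoch_set`.
#' @export
preprocess_eeg <- function(rec, band = c(0.5, 45), notch = 50, target_fs = 500,
                           epoch_length_s = 2, reject_uV = 80, exclude = NULL) {
  rec <- bandpass_filter(rec, band[1], band[2])
  if (!is.null(notch)) rec <- notch_filter(rec, notch)
  if (!is.null(target_fs)) rec <- resample_recording(rec, target_fs)
  rec <- common_average_reference(rec)
  ep <- epoch_recording(rec, epoch_length_s)
  if (!is.null(exclude)) ep <- exclude_epochs(ep, exclude)
  if (!is.null(reject_uV)) ep <- reject_amplitude(ep, reject_uV)
  ep
}

#' @rdname preprocess_eeg
#' @export
preprocess_emg <- function(rec, band = c(20, 400), target_fs = 500,
                           epoch_length_s = 2, exclude = NULL) {
  rec <- bandpass_filter(rec, band[1], band[2])
  if (!is.null(target_fs)) rec <- resample_recording(rec, target_fs)
  ep <- epoch_recording(rec, epoch_length_s)
  if (!is.null(exclude)) ep <- exclude_epochs(ep, exclude)
  ep
}
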