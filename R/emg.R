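# Time-domain surface EMG features: peak-to-peak and RMS amplitude,
# per-epoch feature tables and pre/post change scores.

#' Peak-to-peak amplitude
#'
#' `max(x) - min(x)`: the amplitude range of an EMG segment, indexing the
#' maximum activation swing of the muscle.
#'
#' @param x Non-empty numeric sample vector (microvolts).
#' @return Peak-to-peak amplitude (microvolts, >= 0).
#' @export
#' @examples
#' compute_ptp(c(-3, 0, 5)) # 8
compute_ptp <- function(x) {
  if (length(x) == 0L) abort("Empty signal.")
  if (!is.numeric(x)) abort("Signal must be numeric.")
  max(x) - min(x)
}

#' Root-mean-square amplitude
#'
#' `sqrt(mean(x^2))`: the RMS of an EMG segment, indexing the overall
#' activation strength.
#'
#' @param x Non-empty numeric sample vector (microvolts).
#' @return RMS amplitude (microvolts, >= 0).
#' @export
#' @examples
#' compute_rms(c(3, 4)) # sqrt(12.5)
compute_rms <- function(x) {
  if (length(x) == 0L) abort("Empty signal.")
  if (!is.numeric(x)) abort("Signal must be numeric.")
  sqrt(mean(x^2))
}

#' Per-muscle EMG feature table
#'
#' Computes peak-to-peak and RMS amplitude per kept epoch and channel, then
#' averages across epochs, giving one row per muscle.
#'
#' @param ep An EMG `epoch_set` with at least one kept epoch.
#' @param muscle_labels Channel labels; defaults to those stored in `ep`.
#' @return A tibble with columns `muscle`, `ptp_uV`, `rms_uV`.
#' @export
feature_table <- function(ep, muscle_labels = ep$channel_labels) {
  stopifnot(inherits(ep, "epoch_set"))
  mats <- kept_epoch_matrices(ep)
  if (length(mats) == 0L) abort("No kept epochs: cannot compute EMG features.")
  if (length(muscle_labels) != dim(ep$epochs)[2]) {
    abort("`muscle_labels` must have one entry per channel.")
  }
  ptp <- rowMeans(vapply(mats, function(m) apply(m, 1L, compute_ptp),
                         numeric(length(muscle_labels))))
  rms <- rowMeans(vapply(mats, function(m) apply(m, 1L, compute_rms),
                         numeric(length(muscle_labels))))
  tibble(muscle = muscle_labels, ptp_uV = unname(ptp), rms_uV = unname(rms))
}

#' Pre/post change scores of EMG features
#'
#' Element-wise `post - pre` for every muscle; the change scores used for
#' correlation against microstate-parameter changes.
#'
#' @param pre,post Feature tables from [feature_table()] over the same
#'   muscles (any order).
#' @return A tibble with `muscle`, `ptp_uV`, `rms_uV` holding the deltas.
#' @export
delta_features <- function(pre, post) {
  req <- c("muscle", "ptp_uV", "rms_uV")
  if (!all(req %in% names(pre)) || !all(req %in% names(post))) {
    abort("Feature tables need columns muscle, ptp_uV, rms_uV.")
  }
  if (!setequal(pre$muscle, post$muscle) ||
      anyDuplicated(pre$muscle) || anyDuplicated(post$muscle)) {
    abort("Muscle sets of `pre` and `post` differ.")
  }
  post <- post[match(pre$muscle, post$muscle), ]
  tibble(
    muscle = pre$muscle,
    ptp_uV = post$ptp_uV - pre$ptp_uV,
    rms_uV = post$rms_uV - pre$rms_uV
  )
}
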