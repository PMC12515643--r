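# Global field power and GFP-peak extraction.

#' Global field power
#'
#' GFP at each time point is the spatial standard deviation of the potential
#' map: `sqrt(sum_i (v_i - vbar)^2 / n)` over the `n` electrodes. High GFP
#' marks moments of strong, high signal-to-noise topography.
#'
#' @param x Channels x samples numeric matrix (one epoch), or a [recording()].
#' @param fs Sampling rate in Hz; taken from `x` when it is a recording.
#' @return A `gfp_series`: list with `values` (per-sample GFP, microvolts),
#'   `fs`, and `peak_indices` (filled by [find_gfp_peaks()]).
#' @export
#' @examples
#' compute_gfp(matrix(c(1, -1), ncol = 1), fs = 500)$values # 1
compute_gfp <- function(x, fs = NULL) {
  if (inherits(x, "recording")) {
    fs <- x$fs
    x <- x$data
  }
  if (!is.matrix(x) || nrow(x) < 2L) {
    abort("GFP needs a channels x samples matrix with at least 2 channels.")
  }
  centred <- sweep(x, 2L, colMeans(x))
  structure(
    list(values = sqrt(colMeans(centred^2)), fs = fs, peak_indices = NULL),
    class = "gfp_series"
  )
}

#' @export
print.gfp_series <- function(x, ...) {
  cat(sprintf("<gfp_series> %d samples%s; %s peaks\n", length(x$values),
              if (is.null(x$fs)) "" else sprintf(" @ %g Hz", x$fs),
              if (is.null(x$peak_indices)) "un-extracted" else length(x$peak_indices)))
  invisible(x)
}

#' @export
as_tibble.gfp_series <- function(x, ...) {
  tibble(
    sample = seq_along(x$values),
    gfp_uV = x$values,
    is_peak = seq_along(x$values) %in% (x$peak_indices %||% integer())
  )
}

#' Locate GFP peaks
#'
#' Strict local maxima of the GFP curve; endpoints are never peaks, and a
#' plateau of equal values flanked by lower values contributes its midpoint
#' (rounded down).
#'
#' @param gfp A `gfp_series` from [compute_gfp()], or a bare numeric vector.
#' @return When given a `gfp_series`, the same object with `peak_indices`
#'   filled; when given a vector, the integer peak indices.
#' @export
find_gfp_peaks <- function(gfp) {
  v <- if (inherits(gfp, "gfp_series")) gfp$values else gfp
  if (length(v) < 3L) {
    idx <- integer()
  } else {
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    k <- seq_along(r$values)
    interior <- k > 1L & k < length(r$values)
    is_peak <- interior &
      r$values > c(-Inf, r$values[-length(r$values)]) &
      r$values > c(r$values[-1L], -Inf)
    idx <- as.integer(floor((starts[is_peak] + ends[is_peak]) / 2))
  }
  if (inherits(gfp, "gfp_series")) {
    gfp$peak_indices <- idx
    gfp
  } else {
    idx
  }
}

# GFP-peak topographies of one epoch as a peaks x channels matrix.
peak_maps_of_epoch <- function(m, fs = NULL) {
  g <- find_gfp_peaks(compute_gfp(m, fs))
  t(m[, g$peak_indices, drop = FALSE])
}

#' Collect GFP-peak topographies from an epoch set
#'
#' Extracts the potential map at every GFP peak of every kept epoch; these
#' maps are the samples fed to [modified_kmeans()].
#'
#' @param ep An `epoch_set`.
#' @return A peaks x channels numeric matrix.
#' @export
gfp_peak_maps <- function(ep) {
  stopifnot(inherits(ep, "epoch_set"))
  if (n_kept(ep) == 0L) abort("No kept epochs: cannot extract GFP peaks.")
  maps <- lapply(kept_epoch_matrices(ep), peak_maps_of_epoch, fs = ep$fs)
  out <- do.call(rbind, maps)
  colnames(out) <- ep$channel_labels
  out
}
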