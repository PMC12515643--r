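# Competitive backfitting, class labelling against reference maps,
# minimum-duration smoothing, and the three temporal microstate parameters.

new_label_sequence <- function(labels, fit_corr, fs, K, class_labels = NULL,
                               epoch_index = seq_len(nrow(labels))) {
  structure(
    list(labels = labels, fit_corr = fit_corr, fs = fs, K = K,
         class_labels = class_labels %||% paste0("M", seq_len(K)),
         epoch_index = epoch_index),
    class = "label_sequence"
  )
}

#' @export
print.label_sequence <- function(x, ...) {
  cat(sprintf("<label_sequence> %d epochs x %d samples @ %g Hz, K = %d; mean |r| = %.3f\n",
              nrow(x$labels), ncol(x$labels), x$fs, x$K, mean(x$fit_corr)))
  invisible(x)
}

#' @export
tidy.label_sequence <- function(x, ...) {
  tibble(
    epoch = rep(x$epoch_index, times = ncol(x$labels)),
    sample = rep(seq_len(ncol(x$labels)), each = nrow(x$labels)),
    class = x$class_labels[as.vector(x$labels)],
    fit_corr = as.vector(x$fit_corr)
  ) |> arrange(.data$epoch, .data$sample)
}

#' @export
glance.label_sequence <- function(x, ...) {
  tibble(n_epochs = nrow(x$labels), n_samples = length(x$labels),
         fs = x$fs, K = x$K, mean_fit_corr = mean(x$fit_corr))
}

#' Competitive backfitting of a microstate model
#'
#' Labels every sample of every kept epoch with the microstate class whose
#' template has the highest absolute spatial correlation with the sample's
#' potential map (polarity is ignored). Ties are broken towards the lowest
#' class index; spatially constant samples get correlation 0 and class 1.
#'
#' @param ep An `epoch_set` whose channels match the model montage.
#' @param model A `topography_model`.
#' @return A `label_sequence` with per-sample class indices and absolute fit
#'   correlations.
#' @export
backfit <- function(ep, model) {
  stopifnot(inherits(ep, "epoch_set"), inherits(model, "topography_model"))
  if (dim(ep$epochs)[2] != ncol(model$maps)) {
    abort("Channel count of epochs and model differ.")
  }
  mats <- kept_epoch_matrices(ep)
  if (length(mats) == 0L) abort("No kept epochs to backfit.")
  ns <- dim(ep$epochs)[3]
  labels <- matrix(1L, nrow = length(mats), ncol = ns)
  fit <- matrix(0, nrow = length(mats), ncol = ns)
  Mt <- t(model$maps)                        # channels x K, unit-norm columns
  for (e in seq_along(mats)) {
    m <- mats[[e]]
    centred <- sweep(m, 2L, colMeans(m))
    nrm <- sqrt(colSums(centred^2))
    zero <- nrm == 0
    nrm[zero] <- 1
    R <- crossprod(centred / rep(nrm, each = nrow(centred)), Mt)  # samples x K
    lab <- max.col(abs(R), ties.method = "first")
    r <- abs(R[cbind(seq_len(ns), lab)])
    lab[zero] <- 1L
    r[zero] <- 0
    labels[e, ] <- lab
    fit[e, ] <- r
  }
  new_label_sequence(labels, fit, fs = ep$fs, K = model$K,
                     class_labels = model$class_labels,
                     epoch_index = which(ep$kept))
}

# all injective assignments of model maps (1..K) to reference rows
.assignments <- function(K, n_ref) {
  if (K == 0L) return(list(integer()))
  out <- list()
  rec <- function(chosen, remaining) {
    if (length(chosen) == K) {
      out[[length(out) + 1L]] <<- chosen
      return(invisible())
    }
    for (r in remaining) rec(c(chosen, r), setdiff(remaining, r))
  }
  rec(integer(), seq_len(n_ref))
  out
}

#' Assign canonical class letters to a microstate model
#'
#' Matches model maps to reference topographies (by default the built-in
#' idealized A-E motor-montage maps) by the injective assignment maximising
#' the summed absolute spatial correlation, enumerated exhaustively
#' (K! <= 120 for K = 5). The returned model has its maps reordered to the
#' reference class order A, B, C, ...
#'
#' @param model A `topography_model`.
#' @param references A `topography_model` of reference maps on the same
#'   montage with at least `model$K` maps; defaults to [reference_maps()].
#' @return The relabelled, reordered `topography_model`; the matched absolute
#'   correlations are attached as attribute `"match_abs_corr"`.
#' @export
label_classes <- function(model, references = reference_maps(model$channel_labels)) {
  stopifnot(inherits(model, "topography_model"),
            inherits(references, "topography_model"))
  if (!identical(model$channel_labels, references$channel_labels)) {
    abort("Model and reference montages differ.")
  }
  if (references$K < model$K) {
    abort("Reference model has fewer maps than the model to label.")
  }
  A <- abs(model$maps %*% t(references$maps))   # K x K_ref |corr|
  best <- NULL
  best_sum <- -Inf
  for (asg in .assignments(model$K, references$K)) {
    s <- sum(A[cbind(seq_len(model$K), asg)])
    if (s > best_sum) {
      best_sum <- s
      best <- asg
    }
  }
  ord <- order(best)                            # reference-class order
  ref_labels <- rownames(references$maps)[sort(best)]
  out <- new_topography_model(model$maps[ord, , drop = FALSE],
                              channel_labels = model$channel_labels,
                              class_labels = ref_labels,
                              gev = model$gev, converged = model$converged,
                              n_iter = model$n_iter)
  attr(out, "match_abs_corr") <- A[cbind(seq_len(model$K), best)][ord]
  out
}

# Approximate 2-D scalp positions (x: left -, right +; y: posterior -,
# frontal +) for the 16-channel motor montage.
.montage_xy <- function() {
  m <- rbind(
    F3  = c(-0.35,  0.70), F4  = c( 0.35,  0.70),
    FC5 = c(-0.65,  0.40), FC1 = c(-0.20,  0.40),
    FC2 = c( 0.20,  0.40), FC6 = c( 0.65,  0.40),
    C3  = c(-0.45,  0.00), C1  = c(-0.15,  0.00),
    C2  = c( 0.15,  0.00), C4  = c( 0.45,  0.00),
    CP5 = c(-0.65, -0.40), CP1 = c(-0.20, -0.40),
    CP2 = c( 0.20, -0.40), CP6 = c( 0.65, -0.40),
    P3  = c(-0.35, -0.70), P4  = c( 0.35, -0.70)
  )
  colnames(m) <- c("x", "y")
  m
}

#' Built-in reference topographies for classes A-E
#'
#' Idealized reference maps over the 16-channel motor montage, one Gaussian
#' potential blob per class at its canonical location: A right-frontal,
#' B left-posterior, C left-frontal, D midline frontal, E central-parietal.
#' They are synthetic orientation anchors for [label_classes()], not
#' empirical group templates; users with their own canonical maps should
#' supply them instead.
#'
#' @param channel_labels Montage; must be a subset of the built-in
#'   16-channel motor montage.
#' @param width Gaussian blob width (montage units).
#' @return A `topography_model` with class labels A-E.
#' @export
reference_maps <- function(channel_labels = eeg_montage_16, width = 0.55) {
  xy <- .montage_xy()
  missing <- setdiff(channel_labels, rownames(xy))
  if (length(missing) > 0L) {
    abort(paste0("No built-in coordinates for channel(s): ",
                 paste(missing, collapse = ", "),
                 ". Supply your own reference maps."))
  }
  xy <- xy[channel_labels, , drop = FALSE]
  centres <- rbind(
    A = c( 0.45,  0.55),
    B = c(-0.45, -0.55),
    C = c(-0.45,  0.55),
    D = c( 0.00,  0.65),
    E = c( 0.00, -0.30)
  )
  maps <- t(apply(centres, 1L, function(cc) {
    exp(-((xy[, "x"] - cc[1])^2 + (xy[, "y"] - cc[2])^2) / (2 * width^2))
  }))
  new_topography_model(maps, channel_labels = channel_labels,
                       class_labels = rownames(centres))
}

# run-length encoding of one epoch's labels: tibble(class, length)
.epoch_runs <- function(lab_row) {
  r <- rle(as.integer(lab_row))
  list(class = r$values, length = r$lengths)
}

#' Merge microstate segments shorter than a minimum duration
#'
#' Temporal smoothing: any run of identical labels shorter than
#' `min_duration_ms` is relabelled to the class of its longer neighbouring
#' run (ties go left; runs at epoch edges take their only neighbour),
#' iterating shortest-first until no short run remains or the epoch is a
#' single run. Runs never cross epoch boundaries.
#'
#' @param labels A `label_sequence`.
#' @param min_duration_ms Minimum segment duration in milliseconds; `0`
#'   disables smoothing.
#' @return The smoothed `label_sequence` (fit correlations are kept as-is).
#' @export
smooth_labels <- function(labels, min_duration_ms = 0) {
  stopifnot(inherits(labels, "label_sequence"))
  if (min_duration_ms <= 0) return(labels)
  min_len <- round(min_duration_ms * labels$fs / 1000)
  if (min_len <= 1L) return(labels)
  for (e in seq_len(nrow(labels$labels))) {
    lab <- as.integer(labels$labels[e, ])
    repeat {
      r <- rle(lab)
      if (length(r$lengths) <= 1L) break
      short <- which(r$lengths < min_len)
      if (length(short) == 0L) break
      i <- short[which.min(r$lengths[short])]
      left_len <- if (i > 1L) r$lengths[i - 1L] else -Inf
      right_len <- if (i < length(r$lengths)) r$lengths[i + 1L] else -Inf
      r$values[i] <- if (left_len >= right_len) r$values[i - 1L] else r$values[i + 1L]
      lab <- inverse.rle(r)
    }
    labels$labels[e, ] <- lab
  }
  labels
}

#' Temporal microstate parameters
#'
#' Computes the three standard temporal statistics per microstate class from
#' a label sequence, with runs confined within epochs (no run spans an epoch
#' boundary):
#' * mean duration (ms): average run length times `1000 / fs`;
#' * coverage (%): share of analysed samples carrying the class;
#' * occurrence (1/s): number of runs divided by total analysed seconds.
#'
#' Under the default policy (boundary-truncated runs counted everywhere) the
#' identity `coverage_pct = occurrence_per_s * mean_duration_ms / 10` holds
#' exactly per class. Setting `drop_boundary_runs_from_duration = TRUE`
#' excludes runs touching an epoch edge from the duration average only (some
#' toolchains do this), which breaks the identity for the affected classes.
#'
#' @param labels A `label_sequence`.
#' @param min_duration_ms Optional smoothing applied first via
#'   [smooth_labels()].
#' @param drop_boundary_runs_from_duration See above.
#' @return A tibble with one row per class: `class`, `mean_duration_ms`,
#'   `coverage_pct`, `occurrence_per_s`, `n_runs`. A class that never occurs
#'   has `NA` duration, zero coverage and zero occurrence.
#' @export
#' @examples
#' # one 10-sample epoch "AAAAABBBBB" at 500 Hz:
#' ep_labels <- matrix(rep(1:2, each = 5), nrow = 1)
#' ls <- structure(list(labels = ep_labels,
#'                      fit_corr = matrix(1, 1, 10), fs = 500, K = 2,
#'                      class_labels = c("A", "B"), epoch_index = 1L),
#'                 class = "label_sequence")
#' microstate_parameters(ls) # A: 10 ms, 50%, 50/s
microstate_parameters <- function(labels, min_duration_ms = 0,
                                  drop_boundary_runs_from_duration = FALSE) {
  stopifnot(inherits(labels, "label_sequence"))
  if (length(labels$labels) == 0L) abort("Empty label sequence.")
  labels <- smooth_labels(labels, min_duration_ms)
  K <- labels$K
  ns <- ncol(labels$labels)
  total_samples <- length(labels$labels)
  total_s <- total_samples / labels$fs
  run_class <- integer()
  run_len <- integer()
  run_boundary <- logical()
  for (e in seq_len(nrow(labels$labels))) {
    r <- rle(as.integer(labels$labels[e, ]))
    nr <- length(r$values)
    run_class <- c(run_class, r$values)
    run_len <- c(run_len, r$lengths)
    run_boundary <- c(run_boundary, seq_len(nr) %in% c(1L, nr))
  }
  per_class <- lapply(seq_len(K), function(k) {
    sel <- run_class == k
    n_runs <- sum(sel)
    cov <- sum(run_len[sel]) / total_samples * 100
    occ <- n_runs / total_s
    dur_sel <- if (drop_boundary_runs_from_duration) sel & !run_boundary else sel
    dur <- if (any(dur_sel)) mean(run_len[dur_sel]) * 1000 / labels$fs else NA_real_
    tibble(class = labels$class_labels[k], mean_duration_ms = dur,
           coverage_pct = cov, occurrence_per_s = occ, n_runs = n_runs)
  })
  bind_rows(per_class)
}
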