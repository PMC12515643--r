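# Polarity-invariant (modified) K-means topographic clustering and the
# global explained variance fit criterion.

# Row-wise centring (zero mean across channels). Rows with zero variance
# become all-zero.
.center_rows <- function(X) X - rowMeans(X)

# Row-wise L2 normalisation; zero rows stay zero.
.normalize_rows <- function(X) {
  nrm <- sqrt(rowSums(X^2))
  nrm[nrm == 0] <- 1
  X / nrm
}

# Canonical sign: largest-magnitude element positive (ties: first one).
.canonical_sign <- function(X) {
  s <- apply(X, 1L, function(r) {
    i <- which.max(abs(r))
    if (r[i] < 0) -1 else 1
  })
  X * s
}

#' Spatial correlation between topographic maps
#'
#' Pearson correlation across channels between two potential maps. Under the
#' microstate polarity convention only its absolute value matters.
#'
#' @param a,b Numeric vectors over the same montage.
#' @return Correlation in `[-1, 1]` (0 if either map is spatially constant).
#' @export
spatial_correlation <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

new_topography_model <- function(maps, channel_labels,
                                 class_labels = NULL, gev = NA_real_,
                                 converged = NA, n_iter = NA_integer_) {
  maps <- .canonical_sign(.normalize_rows(.center_rows(maps)))
  colnames(maps) <- channel_labels
  rownames(maps) <- class_labels %||% paste0("M", seq_len(nrow(maps)))
  structure(
    list(maps = maps, channel_labels = channel_labels,
         class_labels = class_labels, K = nrow(maps),
         gev = gev, converged = converged, n_iter = n_iter),
    class = "topography_model"
  )
}

#' @export
print.topography_model <- function(x, ...) {
  cat(sprintf("<topography_model> K = %d over %d channels", x$K,
              length(x$channel_labels)))
  if (!is.null(x$class_labels)) {
    cat(" [classes ", paste(x$class_labels, collapse = ""), "]", sep = "")
  }
  if (!is.na(x$gev)) cat(sprintf("; GEV = %.4f", x$gev))
  cat("\n")
  invisible(x)
}

#' @export
tidy.topography_model <- function(x, ...) {
  tibble(
    class = rep(rownames(x$maps), times = ncol(x$maps)),
    channel = rep(x$channel_labels, each = nrow(x$maps)),
    value = as.vector(x$maps)
  )
}

#' @export
glance.topography_model <- function(x, ...) {
  tibble(K = x$K, n_channels = length(x$channel_labels), gev = x$gev,
         converged = x$converged, n_iter = x$n_iter)
}

# One modified K-means run from a given initialisation.
# Xn: unit-norm zero-mean maps (S x n); w: GFP^2 weights.
.mkmeans_once <- function(X, Xn, w, K, init_idx, max_iter, tol) {
  C <- Xn[init_idx, , drop = FALSE]
  gev_prev <- -Inf
  gev <- 0
  assign <- rep(1L, nrow(Xn))
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    R <- Xn %*% t(C)                       # correlations (rows unit-norm)
    assign <- max.col(R^2, ties.method = "first")
    r_best <- R[cbind(seq_len(nrow(R)), assign)]
    gev <- sum(w * r_best^2) / sum(w)
    for (k in seq_len(K)) {
      members <- which(assign == k)
      if (length(members) == 0L) {
        # re-seed an empty cluster at the worst-fit map
        C[k, ] <- Xn[which.min(abs(r_best)), ]
        next
      }
      M <- X[members, , drop = FALSE]
      ev <- eigen(crossprod(M), symmetric = TRUE)
      ck <- ev$vectors[, 1L]
      C[k, ] <- ck / sqrt(sum(ck^2))
    }
    if (gev - gev_prev < tol * max(abs(gev_prev), 1e-12) && iter > 1L) {
      converged <- TRUE
      break
    }
    gev_prev <- gev
  }
  list(centers = C, gev = gev, assign = assign, converged = converged,
       n_iter = iter)
}

#' Polarity-invariant modified K-means over GFP-peak maps
#'
#' Clusters topographic maps ignoring polarity: each map is assigned to the
#' cluster centre maximising its squared spatial correlation, and centres are
#' updated as the dominant eigenvector of the assigned maps' channel
#' cross-product matrix. Runs are repeated from `n_restarts` random
#' initialisations (maps drawn as initial centres) and the solution with the
#' highest GFP^2-weighted global explained variance is kept. Clusters are
#' returned ordered by decreasing explained variance share, with a canonical
#' sign (largest-magnitude channel positive), making the result a
#' deterministic function of the inputs and `seed`.
#'
#' @param peak_maps Samples x channels matrix of topographies (typically from
#'   [gfp_peak_maps()]). Must contain at least `K` rows.
#' @param K Number of microstate classes (default 5).
#' @param n_restarts Random restarts (default 50).
#' @param seed Integer seed controlling the restarts.
#' @param max_iter,tol Convergence controls: stop when the relative GEV
#'   improvement falls below `tol` or after `max_iter` iterations (with a
#'   warning if no restart converged).
#' @return A `topography_model` with unit-norm zero-mean maps, the achieved
#'   `gev`, and convergence information.
#' @export
modified_kmeans <- function(peak_maps, K = 5, n_restarts = 50, seed = 1,
                            max_iter = 500, tol = 1e-6) {
  if (!is.matrix(peak_maps)) peak_maps <- as.matrix(peak_maps)
  S <- nrow(peak_maps)
  if (S < K) {
    abort(sprintf("Need at least K = %d maps, got %d.", K, S))
  }
  X <- .center_rows(peak_maps)
  nrm2 <- rowSums(X^2)
  w <- nrm2 / ncol(X)                       # proportional to GFP^2
  Xn <- .normalize_rows(X)
  best <- NULL
  withr::with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      init_idx <- sample.int(S, K)
      fit <- .mkmeans_once(X, Xn, w, K, init_idx, max_iter, tol)
      if (is.null(best) || fit$gev > best$gev) best <- fit
    }
  })
  if (!best$converged) {
    warn(sprintf("modified_kmeans: best restart did not converge within %d iterations; returning best-so-far.",
                 max_iter))
  }
  # order clusters by their contribution to explained variance
  r_best <- (Xn %*% t(best$centers))[cbind(seq_len(S), best$assign)]
  contrib <- vapply(seq_len(K), function(k) {
    sum(w[best$assign == k] * r_best[best$assign == k]^2)
  }, numeric(1))
  ord <- order(contrib, decreasing = TRUE)
  new_topography_model(best$centers[ord, , drop = FALSE],
                       channel_labels = colnames(peak_maps) %||%
                         paste0("ch", seq_len(ncol(peak_maps))),
                       gev = best$gev, converged = best$converged,
                       n_iter = best$n_iter)
}

#' Aggregate subject-level models into a group model
#'
#' Pools the template maps of all subject models and re-clusters them with
#' [modified_kmeans()], yielding the group-level microstate model that is
#' then backfitted to every subject.
#'
#' @param subject_models Non-empty list of `topography_model`s on the same
#'   montage.
#' @param K Number of group classes.
#' @param n_restarts,seed Passed to [modified_kmeans()].
#' @return A `topography_model`.
#' @export
aggregate_group_model <- function(subject_models, K = 5, n_restarts = 50,
                                  seed = 1) {
  if (length(subject_models) == 0L) abort("`subject_models` is empty.")
  labs <- subject_models[[1]]$channel_labels
  ok <- vapply(subject_models, function(m) {
    inherits(m, "topography_model") && identical(m$channel_labels, labs)
  }, logical(1))
  if (!all(ok)) abort("All subject models must share one montage.")
  pooled <- do.call(rbind, lapply(subject_models, function(m) m$maps))
  modified_kmeans(pooled, K = K, n_restarts = n_restarts, seed = seed)
}

#' Global explained variance of a labelled fit
#'
#' GFP^2-weighted mean of the squared spatial correlation between each
#' sample's map and its assigned template; the standard criterion for how
#' much topographic variance a microstate model explains.
#'
#' @param ep An `epoch_set`.
#' @param model A `topography_model`.
#' @param labels A `label_sequence` from [backfit()] (or any label matrix
#'   aligned with the kept epochs).
#' @return A single number in `[0, 1]`.
#' @export
global_explained_variance <- function(ep, model, labels) {
  stopifnot(inherits(ep, "epoch_set"), inherits(model, "topography_model"))
  lab <- if (inherits(labels, "label_sequence")) labels$labels else labels
  mats <- kept_epoch_matrices(ep)
  if (length(mats) != nrow(lab)) {
    abort("Label rows do not match the number of kept epochs.")
  }
  num <- 0
  den <- 0
  for (e in seq_along(mats)) {
    m <- mats[[e]]
    centred <- sweep(m, 2L, colMeans(m))
    g2 <- colMeans(centred^2)
    nrm <- sqrt(colSums(centred^2))
    nrm[nrm == 0] <- 1
    r <- colSums(centred / rep(nrm, each = nrow(centred)) *
                   t(model$maps[lab[e, ], , drop = FALSE]))
    num <- num + sum(g2 * r^2)
    den <- den + sum(g2)
  }
  if (den == 0) abort("Total GFP is zero: explained variance undefined.")
  num / den
}
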