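# Shared fixture builders; everything is generated in code.

# a recording whose every channel carries the same signal vector
flat_recording <- function(x, fs = 1000, n_ch = 2, modality = "EEG") {
  recording(matrix(x, nrow = n_ch, ncol = length(x), byrow = TRUE),
            fs = fs, channel_labels = paste0("ch", seq_len(n_ch)),
            modality = modality)
}

# steady-state peak amplitude, measured away from filter edge transients
steady_amp <- function(rec, ch = 1) {
  n <- ncol(rec$data)
  mid <- seq(floor(n * 0.4), floor(n * 0.6))
  max(abs(rec$data[ch, mid]))
}

# wrap a single channels x samples matrix as a 1-epoch epoch_set
matrix_epoch_set <- function(m, fs = 500, modality = "EEG") {
  rec <- recording(m, fs = fs, channel_labels = paste0("ch", seq_len(nrow(m))),
                   modality = modality)
  epoch_recording(rec, ncol(m) / fs)
}

# label_sequence straight from a label matrix
label_seq <- function(labels, fs = 500, K = max(labels),
                      class_labels = LETTERS[seq_len(K)]) {
  new_label_sequence(matrix(as.integer(labels), nrow = NROW(labels)),
                     fit_corr = matrix(1, nrow = NROW(labels), ncol = NCOL(labels)),
                     fs = fs, K = K, class_labels = class_labels)
}

# run-length-encoding oracle for the three temporal parameters
rle_params_oracle <- function(label_matrix, fs, K) {
  total <- length(label_matrix)
  total_s <- total / fs
  lens <- list()
  for (k in seq_len(K)) lens[[k]] <- integer()
  for (e in seq_len(nrow(label_matrix))) {
    r <- rle(as.integer(label_matrix[e, ]))
    for (i in seq_along(r$values)) {
      k <- r$values[i]
      lens[[k]] <- c(lens[[k]], r$lengths[i])
    }
  }
  do.call(rbind, lapply(seq_len(K), function(k) {
    data.frame(
      class_index = k,
      mean_duration_ms = if (length(lens[[k]])) mean(lens[[k]]) * 1000 / fs else NA_real_,
      coverage_pct = sum(lens[[k]]) / total * 100,
      occurrence_per_s = length(lens[[k]]) / total_s
    )
  }))
}
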