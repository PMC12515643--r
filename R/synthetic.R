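# Seeded generators: planted microstate templates, semi-Markov EEG with a
# rectified-alpha amplitude envelope, tone-based EMG with analytic features,
# and the embedded clinical score table.

#' Generate planted microstate template maps
#'
#' Draws `K` random zero-mean, unit-norm topographies over `n_channels`
#' channels, rejecting candidates whose absolute spatial correlation with an
#' already accepted map exceeds `max_abs_corr`, so the planted classes are
#' mutually distinguishable. Deterministic given `seed`.
#'
#' @param n_channels Number of electrodes; must be at least `K + 1`, since
#'   zero-mean maps live in an `n_channels - 1` dimensional space (on 2
#'   channels all zero-mean maps are collinear).
#' @param K Number of template classes.
#' @param seed Integer seed.
#' @param max_abs_corr Pairwise absolute-correlation ceiling (default 0.6).
#' @param channel_labels Optional montage labels (default: the built-in
#'   16-channel motor montage when `n_channels == 16`, else `ch1..chN`).
#' @return A `topography_model` with class labels `A`, `B`, ...
#' @export
make_templates <- function(n_channels, K, seed = 1, max_abs_corr = 0.6,
                           channel_labels = NULL) {
  if (n_channels < K + 1L) {
    abort(sprintf(paste0("Degenerate geometry: %d zero-mean maps on %d channels ",
                         "cannot satisfy pairwise |r| <= %g (need n_channels >= K + 1)."),
                  K, n_channels, max_abs_corr))
  }
  channel_labels <- channel_labels %||%
    (if (n_channels == 16L) eeg_montage_16 else paste0("ch", seq_len(n_channels)))
  maps <- matrix(0, nrow = 0, ncol = n_channels)
  withr::with_seed(seed, {
    tries <- 0L
    while (nrow(maps) < K) {
      tries <- tries + 1L
      if (tries > 1000L * K) {
        abort("Could not place mutually distinguishable templates; relax `max_abs_corr`.")
      }
      cand <- stats::rnorm(n_channels)
      cand <- cand - mean(cand)
      nrm <- sqrt(sum(cand^2))
      if (nrm == 0) next
      cand <- cand / nrm
      if (nrow(maps) == 0L || all(abs(maps %*% cand) <= max_abs_corr)) {
        maps <- rbind(maps, cand)
      }
    }
  })
  new_topography_model(maps, channel_labels = channel_labels,
                       class_labels = LETTERS[seq_len(K)])
}

# planted semi-Markov label path: class drawn proportional to rates with no
# immediate self-transition, dwell ~ gamma(shape, mean = mean_dwell_ms)
.plant_labels <- function(N, fs, class_rates, mean_dwell_ms, dwell_shape) {
  K <- length(class_rates)
  labels <- integer(N)
  pos <- 1L
  cur <- sample.int(K, 1L, prob = class_rates)
  while (pos <= N) {
    mean_samples <- mean_dwell_ms[cur] * fs / 1000
    len <- max(1L, as.integer(round(stats::rgamma(1L, shape = dwell_shape,
                                                  rate = dwell_shape / mean_samples))))
    end <- min(N, pos + len - 1L)
    labels[pos:end] <- cur
    pos <- end + 1L
    if (K > 1L) {
      others <- setdiff(seq_len(K), cur)
      cur <- if (length(others) == 1L) others else
        sample(others, 1L, prob = class_rates[others])
    }
  }
  labels
}

#' Simulate resting-state EEG with a planted microstate sequence
#'
#' Generates a semi-Markov microstate path (class drawn proportional to
#' `class_rates`, never repeating the current class; dwell times gamma with
#' shape `dwell_shape` and the class's mean), emits the active template
#' scaled by a rectified `envelope_hz` sinusoidal amplitude envelope (so GFP
#' peaks occur at roughly `2 * envelope_hz` per second, mimicking occipital
#' alpha), and adds spatially white Gaussian noise at `snr_db`, defined as
#' the ratio of mean squared signal GFP to expected squared noise GFP.
#' `snr_db = Inf` gives a noise-free recording. Deterministic given `seed`.
#'
#' @param templates A `topography_model` of planted maps (e.g.
#'   [make_templates()]).
#' @param class_rates Positive per-class relative occurrence rates.
#' @param mean_dwell_ms Positive per-class mean dwell times (ms).
#' @param snr_db Signal-to-noise ratio in dB on the GFP power ratio.
#' @param fs Sampling rate in Hz.
#' @param duration_s Recording length in seconds.
#' @param seed Integer seed.
#' @param envelope_hz Amplitude-envelope frequency (default 10 Hz).
#' @param dwell_shape Gamma shape of the dwell law (default 2).
#' @param base_amplitude_uV Template scale in microvolts.
#' @return A list with `recording` (a [recording()]) and `ground_truth`, a
#'   `simulation_ground_truth` holding the planted `templates`,
#'   `label_sequence`, per-class planted coverage/occurrence/dwell, `snr_db`
#'   and `seed`.
#' @export
simulate_eeg <- function(templates, class_rates, mean_dwell_ms, snr_db = 10,
                         fs = 500, duration_s = 120, seed = 1,
                         envelope_hz = 10, dwell_shape = 2,
                         base_amplitude_uV = 15) {
  stopifnot(inherits(templates, "topography_model"))
  K <- templates$K
  if (K < 1L) abort("Empty template set.")
  if (length(class_rates) != K || length(mean_dwell_ms) != K) {
    abort("`class_rates` and `mean_dwell_ms` must have one entry per template.")
  }
  if (any(class_rates <= 0) || any(mean_dwell_ms <= 0)) {
    abort("Rates and dwell times must be positive.")
  }
  if (duration_s <= 0 || fs <= 0) abort("`duration_s` and `fs` must be positive.")
  N <- as.integer(round(duration_s * fs))
  n_ch <- length(templates$channel_labels)
  out <- withr::with_seed(seed, {
    labels <- .plant_labels(N, fs, class_rates, mean_dwell_ms, dwell_shape)
    tt <- (seq_len(N) - 1) / fs
    env <- abs(sin(2 * pi * envelope_hz * tt))
    S <- t(templates$maps[labels, , drop = FALSE]) *
      rep(env * base_amplitude_uV, each = n_ch)
    if (is.finite(snr_db)) {
      centred <- sweep(S, 2L, colMeans(S))
      p_sig <- mean(colMeans(centred^2))
      # E[squared noise GFP] = sigma^2 (n-1)/n for iid N(0, sigma^2) channels
      sigma2 <- p_sig / (10^(snr_db / 10)) * n_ch / (n_ch - 1)
      S <- S + matrix(stats::rnorm(length(S), sd = sqrt(sigma2)), nrow = n_ch)
    }
    list(S = S, labels = labels)
  })
  rec <- recording(out$S, fs = fs, channel_labels = templates$channel_labels,
                   modality = "EEG")
  gt <- planted_summary(out$labels, fs, K)
  ground_truth <- structure(
    list(templates = templates, label_sequence = out$labels,
         class_rates = class_rates, mean_dwell_ms = mean_dwell_ms,
         planted = gt, snr_db = snr_db, seed = seed,
         envelope_hz = envelope_hz, dwell_shape = dwell_shape,
         base_amplitude_uV = base_amplitude_uV, fs = fs),
    class = "simulation_ground_truth"
  )
  list(recording = rec, ground_truth = ground_truth)
}

#' Empirical temporal parameters of a planted label path
#'
#' Run-length statistics of a single planted label vector (one continuous
#' path, no epoch boundaries): per class coverage fraction, runs per second,
#' and mean dwell (ms). The identity
#' `coverage = occurrence_per_s * mean_dwell_ms / 1000` holds exactly.
#'
#' @param labels Integer label vector.
#' @param fs Sampling rate in Hz.
#' @param K Number of classes.
#' @return A tibble with `class_index`, `coverage`, `occurrence_per_s`,
#'   `mean_dwell_ms`, `n_runs`.
#' @export
planted_summary <- function(labels, fs, K) {
  r <- rle(as.integer(labels))
  total_s <- length(labels) / fs
  bind_rows(lapply(seq_len(K), function(k) {
    sel <- r$values == k
    tibble(
      class_index = k,
      coverage = sum(r$lengths[sel]) / length(labels),
      occurrence_per_s = sum(sel) / total_s,
      mean_dwell_ms = if (any(sel)) mean(r$lengths[sel]) * 1000 / fs else NA_real_,
      n_runs = sum(sel)
    )
  }))
}

#' @export
print.simulation_ground_truth <- function(x, ...) {
  cat(sprintf("<simulation_ground_truth> K = %d, %d samples @ %g Hz, SNR %s dB, seed %d\n",
              x$templates$K, length(x$label_sequence), x$fs,
              format(x$snr_db), x$seed))
  print(x$planted)
  invisible(x)
}

#' Simulate surface EMG with known analytic features
#'
#' Each channel is a stationary band-limited tone: a sinusoid of the given
#' amplitude at an integer frequency inside the surface-EMG band (default
#' frequencies are spread over 53-143 Hz). Over a whole number of periods
#' the analytic features are exact: peak-to-peak `2 * a` and RMS
#' `a / sqrt(2)`. Optional additive Gaussian noise (`noise_sd`, default 0)
#' uses `seed`.
#'
#' @param n_channels Number of channels.
#' @param amplitudes Non-negative per-channel amplitudes (microvolts);
#'   recycled scalars allowed.
#' @param fs Sampling rate in Hz.
#' @param duration_s Duration in seconds (integer seconds give whole periods
#'   for the integer default frequencies).
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @param freqs_hz Optional per-channel tone frequencies (Hz).
#' @param channel_labels Optional labels (default: the 10-muscle montage when
#'   `n_channels == 10`).
#' @param noise_sd Additive white-noise standard deviation (microvolts).
#' @return A list with `recording` (modality EMG) and `features`, a tibble of
#'   the analytic `ptp_uV` and `rms_uV` per channel.
#' @export
simulate_emg <- function(n_channels = 10, amplitudes = 50, fs = 1000,
                         duration_s = 10, seed = 1, freqs_hz = NULL,
                         channel_labels = NULL, noise_sd = 0) {
  amplitudes <- rep_len(amplitudes, n_channels)
  if (any(amplitudes < 0)) abort("Amplitudes must be non-negative.")
  if (duration_s <= 0 || fs <= 0) abort("`duration_s` and `fs` must be positive.")
  freqs_hz <- freqs_hz %||% (53 + 10 * (seq_len(n_channels) - 1L))
  freqs_hz <- rep_len(freqs_hz, n_channels)
  if (any(freqs_hz >= fs / 2)) abort("Tone frequencies must be below Nyquist.")
  channel_labels <- channel_labels %||%
    (if (n_channels == 10L) emg_muscles_10 else paste0("emg", seq_len(n_channels)))
  N <- as.integer(round(duration_s * fs))
  tt <- (seq_len(N) - 1) / fs
  data <- t(vapply(seq_len(n_channels), function(i) {
    amplitudes[i] * sin(2 * pi * freqs_hz[i] * tt)
  }, numeric(N)))
  if (noise_sd > 0) {
    data <- data + withr::with_seed(seed, {
      matrix(stats::rnorm(length(data), sd = noise_sd), nrow = n_channels)
    })
  }
  rec <- recording(data, fs = fs, channel_labels = channel_labels,
                   modality = "EMG")
  features <- tibble(
    muscle = channel_labels,
    ptp_uV = 2 * amplitudes,
    rms_uV = amplitudes / sqrt(2)
  )
  list(recording = rec, features = features)
}

#' Clinical outcome table of the 20-patient rTMS cohort
#'
#' Per-subject demographic and clinical outcome scores of the embedded
#' 20-patient stroke cohort treated with 10 Hz rTMS: sex, age, affected side,
#' stroke type, and Fugl-Meyer Assessment (upper extremity, 0-66) and Action
#' Research Arm Test (0-57) scores before and after treatment.
#'
#' @return A tibble with 20 rows and columns `subject`, `sex`, `age`,
#'   `affected_side`, `stroke_type`, `fma_ue_pre`, `fma_ue_post`,
#'   `arat_pre`, `arat_post`.
#' @export
#' @examples
#' scores <- clinical_scores()
#' mean(scores$age) # 63.10
clinical_scores <- function() {
  path <- system.file("extdata", "stroke_clinical_scores.csv",
                      package = "msrehab", mustWork = TRUE)
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' rTMS protocol pulse count
#'
#' Total pulses delivered by a repetitive-stimulation protocol:
#' `pulse_rate_hz * train_duration_s * n_trains`. The embedded cohort's
#' protocol (10 Hz trains of 2 s, 60 trains per session) delivers 1200
#' pulses.
#'
#' @param pulse_rate_hz Stimulation frequency (Hz).
#' @param train_duration_s Train duration (s).
#' @param n_trains Number of trains per session.
#' @return Total pulse count.
#' @export
stimulation_pulses <- function(pulse_rate_hz = 10, train_duration_s = 2,
                               n_trains = 60) {
  if (pulse_rate_hz <= 0 || train_duration_s <= 0 || n_trains <= 0) {
    abort("Protocol parameters must be positive.")
  }
  pulse_rate_hz * train_duration_s * n_trains
}
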