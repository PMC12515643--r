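# Reproducible end-to-end commands: structured configuration, seeded
# simulation of a two-group study, and the analysis chain from raw
# recordings to parameter tables, feature tables and statistical reports.

#' Pipeline configuration
#'
#' Bundles every tunable of the pipeline with the acquisition-protocol
#' defaults: EEG band 0.5-45 Hz with a 50 Hz notch, EMG band 20-400 Hz,
#' downsampling to 500 Hz, 2-s epochs, +/- 80 uV rejection, K = 5 microstate
#' classes with 50 restarts, and Benjamini-Hochberg correction. Validated on
#' construction.
#'
#' @param seed Integer master seed.
#' @param eeg_band,emg_band Band edges in Hz.
#' @param notch Notch frequency in Hz (`NULL` to skip).
#' @param resample_fs Downsampling target in Hz.
#' @param epoch_length_s Epoch length in seconds.
#' @param reject_uV Amplitude-rejection threshold in microvolts.
#' @param k Number of microstate classes.
#' @param restarts Modified K-means restarts.
#' @param min_duration_ms Minimum microstate segment duration for
#'   [smooth_labels()] (0 = off).
#' @param p_adjust_method `"fdr_bh"` or `"bonferroni"`.
#' @param welch Use Welch's t for independent comparisons.
#' @param n_subjects_per_group,duration_s,snr_db Simulation settings used by
#'   [cmd_simulate()].
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, eeg_band = c(0.5, 45), emg_band = c(20, 400),
                            notch = 50, resample_fs = 500, epoch_length_s = 2,
                            reject_uV = 80, k = 5, restarts = 50,
                            min_duration_ms = 0, p_adjust_method = "fdr_bh",
                            welch = FALSE, n_subjects_per_group = 3,
                            duration_s = 30, snr_db = 10) {
  cfg <- list(seed = seed, eeg_band = eeg_band, emg_band = emg_band,
              notch = notch, resample_fs = resample_fs,
              epoch_length_s = epoch_length_s, reject_uV = reject_uV,
              k = k, restarts = restarts, min_duration_ms = min_duration_ms,
              p_adjust_method = p_adjust_method, welch = welch,
              n_subjects_per_group = n_subjects_per_group,
              duration_s = duration_s, snr_db = snr_db)
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
  cfg
}

#' @rdname pipeline_config
#' @param cfg A `pipeline_config`.
#' @export
validate_config <- function(cfg) {
  check <- function(ok, msg) if (!ok) abort(paste0("Invalid config: ", msg))
  check(is.numeric(cfg$seed) && length(cfg$seed) == 1L, "seed must be a single integer.")
  check(length(cfg$eeg_band) == 2L && cfg$eeg_band[1] > 0 &&
          cfg$eeg_band[2] > cfg$eeg_band[1], "eeg_band must satisfy 0 < low < high.")
  check(length(cfg$emg_band) == 2L && cfg$emg_band[1] > 0 &&
          cfg$emg_band[2] > cfg$emg_band[1], "emg_band must satisfy 0 < low < high.")
  check(is.null(cfg$notch) || cfg$notch > 0, "notch must be positive or NULL.")
  check(cfg$resample_fs > 0, "resample_fs must be positive.")
  check(cfg$epoch_length_s > 0, "epoch_length_s must be positive.")
  check(cfg$reject_uV > 0, "reject_uV must be positive.")
  check(is.numeric(cfg$k) && cfg$k >= 1, "k must be >= 1.")
  check(cfg$restarts >= 1, "restarts must be >= 1.")
  check(cfg$min_duration_ms >= 0, "min_duration_ms must be >= 0.")
  check(cfg$p_adjust_method %in% c("fdr_bh", "bonferroni"),
        "p_adjust_method must be fdr_bh or bonferroni.")
  check(cfg$n_subjects_per_group >= 1, "n_subjects_per_group must be >= 1.")
  check(cfg$duration_s > 0, "duration_s must be positive.")
  invisible(cfg)
}

#' @rdname pipeline_config
#' @param path JSON file path.
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

.config_hash <- function(cfg) {
  # order-stable structural fingerprint (no external digest dependency)
  s <- jsonlite::toJSON(unclass(cfg)[order(names(unclass(cfg)))],
                        auto_unbox = TRUE, digits = NA)
  sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 97 + 1)) %% 1e9
}

.log_stage <- function(stage, ...) {
  kv <- c(...)
  msg <- paste0("stage=", stage)
  if (length(kv)) {
    msg <- paste(msg, paste(names(kv), unname(kv), sep = "=", collapse = " "))
  }
  message(msg)
}

.provenance <- function(cfg) {
  list(config_hash = .config_hash(cfg), seed = cfg$seed,
       package_version = as.character(utils::packageVersion("msrehab")))
}

.write_table <- function(df, path) {
  utils::write.csv(as.data.frame(df), path, row.names = FALSE)
  path
}

#' Simulate a two-group study to disk
#'
#' Generates, deterministically from `cfg$seed`, a planted-template EEG and a
#' tone-based EMG recording per subject for a "patient" and a "control"
#' group, writes them as CSV (+ JSON sidecars), the planted ground truth as
#' CSV, the clinical score fixture, and a provenance sidecar.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the character vector of files written.
#' @export
cmd_simulate <- function(cfg, out_dir) {
  validate_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  templates <- make_templates(16, cfg$k, seed = cfg$seed)
  rates <- rep(1, cfg$k)
  dwell <- rep(80, cfg$k)
  .log_stage("simulate", k = cfg$k, seed = cfg$seed,
             n_per_group = cfg$n_subjects_per_group)
  for (grp in c("patient", "control")) {
    for (i in seq_len(cfg$n_subjects_per_group)) {
      sub_seed <- cfg$seed + 1000L * (grp == "control") + i
      sim <- simulate_eeg(templates, rates, dwell, snr_db = cfg$snr_db,
                          fs = 1000, duration_s = cfg$duration_s,
                          seed = sub_seed)
      p <- file.path(out_dir, sprintf("eeg_%s_%02d.csv", grp, i))
      write_recording(sim$recording, p)
      gt <- sim$ground_truth$planted
      gt$class <- templates$class_labels[gt$class_index]
      pg <- file.path(out_dir, sprintf("ground_truth_%s_%02d.csv", grp, i))
      .write_table(gt, pg)
      emg <- simulate_emg(10, amplitudes = 30 + 5 * seq_len(10), fs = 1000,
                          duration_s = cfg$duration_s, seed = sub_seed)
      pe <- file.path(out_dir, sprintf("emg_%s_%02d.csv", grp, i))
      write_recording(emg$recording, pe)
      files <- c(files, p, paste0(p, ".json"), pg, pe, paste0(pe, ".json"))
    }
  }
  fx <- file.path(out_dir, "clinical_scores.csv")
  .write_table(clinical_scores(), fx)
  prov <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(.provenance(cfg), prov, auto_unbox = TRUE, digits = NA)
  files <- c(files, fx, prov)
  .log_stage("simulate_done", files = length(files))
  invisible(files)
}

#' Run the analysis chain over a simulated or recorded study
#'
#' Orchestrates, per group found in `in_dir` (files `eeg_<group>_<i>.csv` as
#' written by [cmd_simulate()]): preprocessing (band-pass, notch, resample,
#' common average reference, epoching, amplitude rejection), per-subject
#' modified K-means on GFP-peak maps, group-template aggregation, canonical
#' A-E labelling, backfitting, and temporal parameter extraction; EMG
#' feature tables; and the clinical outcome report from the score table.
#' Writes CSV reports plus a JSON provenance sidecar and logs stage-level
#' `key=value` counts.
#'
#' @param cfg A [pipeline_config()].
#' @param in_dir Directory holding the recordings and score table.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named list with the in-memory results:
#'   `group_models`, `parameters`, `emg_features`, `clinical`.
#' @export
cmd_analyze <- function(cfg, in_dir, out_dir) {
  validate_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  eeg_files <- sort(list.files(in_dir, pattern = "^eeg_.*\\.csv$",
                               full.names = TRUE))
  if (length(eeg_files) == 0L) abort(sprintf("No EEG recordings found in %s.", in_dir))
  info <- regmatches(basename(eeg_files),
                     regexec("^eeg_([a-z]+)_([0-9]+)\\.csv$", basename(eeg_files)))
  groups <- vapply(info, `[`, character(1), 2L)
  refs <- reference_maps()
  params_all <- list()
  models <- list()
  for (grp in unique(groups)) {
    grp_files <- eeg_files[groups == grp]
    subject_models <- list()
    epoch_sets <- list()
    for (f in grp_files) {
      rec <- read_recording(f)
      ep <- preprocess_eeg(rec, band = cfg$eeg_band, notch = cfg$notch,
                           target_fs = cfg$resample_fs,
                           epoch_length_s = cfg$epoch_length_s,
                           reject_uV = cfg$reject_uV)
      if (n_kept(ep) == 0L) {
        abort(sprintf("Stage preprocess: all epochs rejected for %s.", basename(f)))
      }
      pm <- gfp_peak_maps(ep)
      .log_stage("preprocess", file = basename(f), epochs_kept = n_kept(ep),
                 epochs_rejected = sum(!ep$kept), gfp_peaks = nrow(pm))
      subject_models[[f]] <- modified_kmeans(pm, K = cfg$k,
                                             n_restarts = cfg$restarts,
                                             seed = cfg$seed)
      epoch_sets[[f]] <- ep
    }
    gm <- aggregate_group_model(subject_models, K = cfg$k,
                                n_restarts = cfg$restarts, seed = cfg$seed)
    gm <- label_classes(gm, refs)
    .log_stage("microstates", group = grp, gev = sprintf("%.4f", gm$gev))
    models[[grp]] <- gm
    for (f in grp_files) {
      ls <- backfit(epoch_sets[[f]], gm)
      pars <- microstate_parameters(ls, min_duration_ms = cfg$min_duration_ms)
      pars$subject <- sub("\\.csv$", "", basename(f))
      pars$group <- grp
      params_all[[f]] <- pars
    }
  }
  parameters <- bind_rows(params_all)
  .write_table(parameters, file.path(out_dir, "microstate_parameters.csv"))
  tidy_models <- bind_rows(lapply(names(models), function(g) {
    tm <- generics::tidy(models[[g]])
    tm$group <- g
    tm
  }))
  .write_table(tidy_models, file.path(out_dir, "group_templates.csv"))

  emg_files <- sort(list.files(in_dir, pattern = "^emg_.*\\.csv$",
                               full.names = TRUE))
  emg_features <- NULL
  if (length(emg_files) > 0L) {
    feats <- lapply(emg_files, function(f) {
      rec <- read_recording(f)
      ep <- preprocess_emg(rec, band = cfg$emg_band,
                           target_fs = cfg$resample_fs,
                           epoch_length_s = cfg$epoch_length_s)
      ft <- feature_table(ep)
      ft$subject <- sub("\\.csv$", "", basename(f))
      ft
    })
    emg_features <- bind_rows(feats)
    .write_table(emg_features, file.path(out_dir, "emg_features.csv"))
    .log_stage("emg_features", files = length(emg_files))
  }

  clinical <- NULL
  score_path <- file.path(in_dir, "clinical_scores.csv")
  if (file.exists(score_path)) {
    scores <- as_tibble(utils::read.csv(score_path))
    clinical <- clinical_outcomes(scores)
    .write_table(clinical, file.path(out_dir, "clinical_outcomes.csv"))
    .log_stage("clinical", outcomes = nrow(clinical))
  }

  jsonlite::write_json(.provenance(cfg), file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  .log_stage("analyze_done", groups = length(models))
  invisible(list(group_models = models, parameters = parameters,
                 emg_features = emg_features, clinical = clinical))
}
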