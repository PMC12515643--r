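test_that("planted templates satisfy the construction constraints and are seeded", {
  tm <- make_templates(16, 5, seed = 1)
  expect_s3_class(tm, "topography_model")
  expect_equal(nrow(tm$maps), 5)
  expect_equal(unname(rowMeans(tm$maps)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(rowSums(tm$maps^2)), rep(1, 5), tolerance = 1e-12)
  cors <- tm$maps %*% t(tm$maps)
  expect_true(all(abs(cors[upper.tri(cors)]) <= 0.6))
  tm2 <- make_templates(16, 5, seed = 7)
  tm3 <- make_templates(16, 5, seed = 7)
  expect_identical(tm2$maps, tm3$maps)
  expect_false(isTRUE(all.equal(tm$maps, tm2$maps)))
})

test_that("template generation refuses degenerate zero-mean geometries", {
  expect_error(make_templates(2, 2, seed = 1), "[Dd]egenerate")
  expect_error(make_templates(5, 5, seed = 1), "[Dd]egenerate")
})

test_that("noise-free simulation is labelled perfectly at GFP peaks by the true templates", {
  tm <- make_templates(16, 4, seed = 3)
  sim <- simulate_eeg(tm, rep(1, 4), rep(80, 4), snr_db = Inf, fs = 500,
                      duration_s = 12, seed = 5)
  ep <- epoch_recording(common_average_reference(sim$recording), 2)
  ls <- backfit(ep, tm)
  gt <- sim$ground_truth$label_sequence
  ns <- dim(ep$epochs)[3]
  hits <- unlist(lapply(seq_len(nrow(ls$labels)), function(e) {
    m <- matrix(ep$epochs[e, , ], nrow = dim(ep$epochs)[2])
    pk <- find_gfp_peaks(compute_gfp(m, ep$fs))$peak_indices
    ls$labels[e, pk] == gt[(e - 1) * ns + pk]
  }))
  expect_gt(length(hits), 100)
  expect_equal(mean(hits), 1)
})

test_that("empirical coverage of the planted chain matches the semi-Markov stationary law", {
  # three classes, rates 2:1:1, equal dwell means: coverage follows the
  # stationary distribution of the no-self-transition run chain
  tm <- make_templates(16, 3, seed = 2)
  rates <- c(2, 1, 1)
  sim <- simulate_eeg(tm, rates, rep(80, 3), snr_db = Inf, fs = 500,
                      duration_s = 120, seed = 11)
  r <- rates / sum(rates)
  P <- outer(seq_len(3), seq_len(3), function(i, j) r[j] / (1 - r[i]))
  diag(P) <- 0
  ev <- eigen(t(P))
  pi_run <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  pi_run <- pi_run / sum(pi_run)        # run-frequency; equal dwells => coverage
  emp <- sim$ground_truth$planted$coverage
  expect_true(all(abs(emp - pi_run) < 0.03))
})

test_that("planted ground truth obeys the coverage identity and sums to one", {
  tm <- make_templates(16, 5, seed = 4)
  sim <- simulate_eeg(tm, c(2, 1, 1, 1, 1), c(60, 80, 100, 80, 60),
                      snr_db = 5, fs = 500, duration_s = 30, seed = 6)
  gt <- sim$ground_truth$planted
  expect_equal(sum(gt$coverage), 1, tolerance = 1e-12)
  expect_equal(gt$coverage,
               gt$occurrence_per_s * gt$mean_dwell_ms / 1000,
               tolerance = 1e-12)
  expect_equal(length(sim$ground_truth$label_sequence),
               ncol(sim$recording$data))
})

test_that("EEG simulation is deterministic in the seed and validates arguments", {
  tm <- make_templates(16, 3, seed = 2)
  a <- simulate_eeg(tm, rep(1, 3), rep(70, 3), snr_db = 8, fs = 250,
                    duration_s = 4, seed = 9)
  b <- simulate_eeg(tm, rep(1, 3), rep(70, 3), snr_db = 8, fs = 250,
                    duration_s = 4, seed = 9)
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$ground_truth$label_sequence, b$ground_truth$label_sequence)
  expect_error(simulate_eeg(tm, rep(1, 3), rep(70, 3), duration_s = -1, seed = 1),
               "positive")
  expect_error(simulate_eeg(tm, c(1, -1, 1), rep(70, 3), duration_s = 1, seed = 1),
               "positive")
  expect_error(simulate_eeg(tm, rep(1, 2), rep(70, 3), duration_s = 1, seed = 1),
               "per template")
})

test_that("simulated EMG has the analytic closed-form features", {
  sim <- simulate_emg(n_channels = 3, amplitudes = c(50, 20, 0), fs = 1000,
                      duration_s = 2, seed = 1)
  x <- sim$recording$data
  expect_equal(compute_ptp(x[1, ]), 100, tolerance = 1e-9)
  expect_equal(compute_rms(x[1, ]), 50 / sqrt(2), tolerance = 0.005 * 50 / sqrt(2))
  expect_equal(compute_ptp(x[3, ]), 0)
  expect_equal(compute_rms(x[3, ]), 0)
  expect_equal(sim$features$ptp_uV, c(100, 40, 0))
  expect_equal(sim$features$rms_uV, c(50, 20, 0) / sqrt(2))
  expect_error(simulate_emg(2, amplitudes = c(-1, 1), duration_s = 1),
               "non-negative")
  a <- simulate_emg(4, 30, duration_s = 1, seed = 3, noise_sd = 1)
  b <- simulate_emg(4, 30, duration_s = 1, seed = 3, noise_sd = 1)
  expect_identical(a$recording$data, b$recording$data)
})

test_that("the clinical score fixture reproduces the printed cohort", {
  sc <- clinical_scores()
  expect_equal(nrow(sc), 20)
  expect_equal(sc$fma_ue_pre[1], 4)
  expect_equal(sc$fma_ue_post[1], 7)
  expect_equal(sc$arat_pre[1], 0)
  expect_equal(sc$arat_post[1], 0)
  expect_equal(mean(sc$age), 63.10)
  expect_equal(mean(sc$fma_ue_pre), 31.50)
})
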