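test_that("backfitting labels template samples with their own class at |r| = 1", {
  tm <- make_templates(16, 5, seed = 1)
  lab <- rep(1:5, 24)
  ep <- matrix_epoch_set(t(tm$maps[lab, ]) * 3, fs = 60)
  ls <- backfit(ep, tm)
  expect_equal(as.vector(ls$labels), lab)
  expect_equal(as.vector(ls$fit_corr), rep(1, length(lab)), tolerance = 1e-9)
  # sign-flipped samples get the same label (polarity ignored)
  ep_neg <- matrix_epoch_set(-t(tm$maps[lab, ]), fs = 60)
  expect_equal(backfit(ep_neg, tm)$labels, ls$labels)
  bad <- matrix_epoch_set(matrix(rnorm(8 * 120), nrow = 8), fs = 60)
  expect_error(backfit(bad, tm), "[Cc]hannel")
})

test_that("backfit equals the exhaustive per-sample argmax oracle", {
  tm <- make_templates(16, 5, seed = 2)
  set.seed(99)
  m <- matrix(rnorm(16 * 1000), nrow = 16)
  ep <- matrix_epoch_set(m, fs = 500)
  ls <- backfit(ep, tm)
  oracle <- vapply(seq_len(1000), function(i) {
    r <- abs(apply(tm$maps, 1, spatial_correlation, b = m[, i]))
    which.max(r)  # first maximum = lowest class index on ties
  }, integer(1))
  expect_equal(as.vector(ls$labels), as.vector(oracle))
  oracle_r <- vapply(seq_len(1000), function(i) {
    max(abs(apply(tm$maps, 1, spatial_correlation, b = m[, i])))
  }, numeric(1))
  expect_equal(as.vector(ls$fit_corr), oracle_r, tolerance = 1e-12)
})

test_that("class labelling recovers permutations and ignores polarity", {
  refs <- reference_maps()
  ident <- label_classes(refs, refs)
  expect_identical(rownames(ident$maps), LETTERS[1:5])
  expect_equal(attr(ident, "match_abs_corr"), rep(1, 5), tolerance = 1e-9)
  # shuffled and sign-flipped model maps come back in reference order
  perm <- c(3, 5, 1, 4, 2)
  shuffled <- new_topography_model(refs$maps[perm, ] * c(1, -1, 1, -1, 1),
                                   channel_labels = refs$channel_labels)
  relab <- label_classes(shuffled, refs)
  expect_identical(rownames(relab$maps), LETTERS[1:5])
  agree <- abs(vapply(1:5, function(k) {
    spatial_correlation(relab$maps[k, ], refs$maps[k, ])
  }, numeric(1)))
  expect_equal(agree, rep(1, 5), tolerance = 1e-9)
  other <- make_templates(8, 3, seed = 1)
  expect_error(label_classes(other, refs), "montage")
})

test_that("temporal parameters match hand counts and the coverage identity", {
  # one 10-sample epoch 'AAAAABBBBB' at 500 Hz
  ls <- label_seq(matrix(rep(1:2, each = 5), nrow = 1), fs = 500)
  pars <- microstate_parameters(ls)
  expect_equal(pars$mean_duration_ms, c(10, 10))
  expect_equal(pars$coverage_pct, c(50, 50))
  expect_equal(pars$occurrence_per_s, c(50, 50))
  expect_equal(pars$coverage_pct,
               pars$occurrence_per_s * pars$mean_duration_ms / 10)
  # a single class filling one 2-s epoch
  ls2 <- label_seq(matrix(1L, nrow = 1, ncol = 1000), fs = 500, K = 1)
  pars2 <- microstate_parameters(ls2)
  expect_equal(pars2$coverage_pct, 100)
  expect_equal(pars2$occurrence_per_s, 0.5)
  expect_equal(pars2$mean_duration_ms, 2000)
  # absent class: NA duration, zero coverage and occurrence
  ls3 <- label_seq(matrix(1L, nrow = 1, ncol = 10), fs = 500, K = 2)
  pars3 <- microstate_parameters(ls3)
  expect_true(is.na(pars3$mean_duration_ms[2]))
  expect_equal(pars3$coverage_pct[2], 0)
  expect_equal(pars3$occurrence_per_s[2], 0)
})

test_that("temporal parameters equal a run-length-encoding oracle on random labels", {
  set.seed(55)
  for (rep in 1:3) {
    labm <- matrix(sample.int(4, 3 * 500, replace = TRUE,
                              prob = c(0.4, 0.3, 0.2, 0.1)), nrow = 3)
    ls <- label_seq(labm, fs = 250, K = 4)
    pars <- microstate_parameters(ls)
    oracle <- rle_params_oracle(labm, fs = 250, K = 4)
    expect_equal(pars$mean_duration_ms, oracle$mean_duration_ms)
    expect_equal(pars$coverage_pct, oracle$coverage_pct)
    expect_equal(pars$occurrence_per_s, oracle$occurrence_per_s)
    expect_equal(sum(pars$coverage_pct), 100, tolerance = 1e-9)
    expect_equal(pars$coverage_pct,
                 pars$occurrence_per_s * pars$mean_duration_ms / 10,
                 tolerance = 1e-9)
  }
})

test_that("runs never span epoch boundaries", {
  # same class at the boundary of two epochs counts as two runs
  labm <- matrix(1L, nrow = 2, ncol = 100)
  ls <- label_seq(labm, fs = 100, K = 1)
  pars <- microstate_parameters(ls)
  expect_equal(pars$n_runs, 2L)
  expect_equal(pars$mean_duration_ms, 1000)
})

test_that("boundary runs can be excluded from the duration average only", {
  labm <- matrix(c(rep(1L, 3), rep(2L, 4), rep(1L, 3)), nrow = 1)
  ls <- label_seq(labm, fs = 100, K = 2)
  def <- microstate_parameters(ls)
  alt <- microstate_parameters(ls, drop_boundary_runs_from_duration = TRUE)
  expect_equal(def$mean_duration_ms[1], 30)        # both boundary runs counted
  expect_true(is.na(alt$mean_duration_ms[1]))      # class 1 only has boundary runs
  expect_equal(alt$mean_duration_ms[2], def$mean_duration_ms[2])
  expect_equal(alt$coverage_pct, def$coverage_pct) # coverage/occurrence unchanged
  expect_equal(alt$occurrence_per_s, def$occurrence_per_s)
})

test_that("minimum-duration smoothing merges flickers into their neighbours", {
  lab <- c(rep(1L, 40), 2L, rep(1L, 40), rep(3L, 40))
  ls <- label_seq(matrix(lab, nrow = 1), fs = 500, K = 3)
  sm <- smooth_labels(ls, min_duration_ms = 10)  # 5 samples at 500 Hz
  expect_equal(as.vector(sm$labels), c(rep(1L, 81), rep(3L, 40)))
  # smoothing off is the identity
  expect_identical(smooth_labels(ls, 0)$labels, ls$labels)
})

test_that("polarity invariance: sign flips change no label and no parameter", {
  tm <- make_templates(16, 4, seed = 31)
  sim <- simulate_eeg(tm, rep(1, 4), rep(60, 4), snr_db = 15, fs = 250,
                      duration_s = 8, seed = 7)
  ep <- epoch_recording(common_average_reference(sim$recording), 2)
  ls <- backfit(ep, tm)
  # flip one whole epoch
  ep_flip <- ep
  ep_flip$epochs[2, , ] <- -ep_flip$epochs[2, , ]
  expect_identical(backfit(ep_flip, tm)$labels, ls$labels)
  # flip one template
  tm_flip <- tm
  tm_flip$maps[3, ] <- -tm_flip$maps[3, ]
  expect_identical(backfit(ep, tm_flip)$labels, ls$labels)
  expect_equal(microstate_parameters(backfit(ep_flip, tm_flip)),
               microstate_parameters(ls))
})
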