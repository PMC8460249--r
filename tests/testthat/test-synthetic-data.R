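test_that("ground truth is deterministic and respects the regime structure", {
  spec <- neuron_spec("TYPE_I", 11, seed = 7)
  gt1 <- sample_ground_truth(spec)
  gt2 <- sample_ground_truth(spec)
  expect_identical(gt1, gt2)

  # spiking regime: every row is a positive multiple of the shared tuning,
  # hence all rows share one rank order
  d <- gt1$shared_tuning
  for (g in seq_len(nrow(gt1$response_matrix))) {
    row <- gt1$response_matrix[g, ]
    expect_equal(unname(row / max(row)), d / max(d), tolerance = 1e-12)
    expect_equal(unname(rank(row)), rank(d))
  }
  expect_true(all(gt1$response_matrix >= 0))

  # grouped regime: private tunings shared within round-robin groups
  gt3 <- sample_ground_truth(neuron_spec("TYPE_IIA1", 9, seed = 3))
  expect_identical(gt3$group_assignment, rep(1:3, 3))
  expect_identical(gt3$private_tunings[1, ], gt3$private_tunings[4, ])
  expect_false(all(gt3$private_tunings[1, ] == gt3$private_tunings[2, ]))

  expect_error(neuron_spec("TYPE_IIB", 9, seed = 1, shared_weight_rho = 1.2),
               "0, 1")
  expect_error(neuron_spec("TYPE_I", 8, seed = 1), "9")
})

test_that("independent tunings (rho = 0) are uncorrelated in expectation", {
  rs <- vapply(1:1000, function(s) {
    gt <- sample_ground_truth(neuron_spec("TYPE_IIB", 9, seed = s,
                                          shared_weight_rho = 0))
    spearman_r(gt$response_matrix[1, ], gt$response_matrix[2, ])
  }, 0)
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("synthesize_trace follows the stated signal model", {
  acq <- quiet_acq()
  tx <- time_axis(acq)
  B <- acq$baseline_fluorescence_mean

  # amplitude 0, no noise: the pure bleaching curve
  f0 <- synthesize_trace(0, acq, rng_seed = 1)
  expect_equal(f0, B * bleach_profile(tx, acq), tolerance = 1e-12)

  # after dividing out the bleach, the peak equals amplitude x sampled
  # kernel maximum (re-derived here on the frame grid)
  f <- synthesize_trace(0.5, acq, rng_seed = 1)
  corr <- f / (B * bleach_profile(tx, acq)) - 1
  s <- pmax(tx - acq$stimulus_onset, 0)
  k_raw <- (1 - exp(-s / 0.1)) * exp(-s / 1.5)
  s_pk <- 0.1 * log(1 + 1.5 / 0.1)
  k <- ifelse(tx < acq$stimulus_onset, 0,
              k_raw / ((1 - exp(-s_pk / 0.1)) * exp(-s_pk / 1.5)))
  expect_equal(max(corr), 0.5 * max(k), tolerance = 1e-10)

  # the noise draw has the declared SD (property of Gaussian sampling)
  acqn <- acquisition_params(noise_sigma = 5)
  fn <- synthesize_trace(0.5, acqn, rng_seed = 42)
  resid <- fn - synthesize_trace(0.5, quiet_acq())
  expect_lt(abs(sd(resid) - 5) / 5, 0.2)

  expect_error(synthesize_trace(-1, acq), "amplitude")
})

test_that("recordings are reproducible, positive, and trialwise consistent", {
  spec <- neuron_spec("TYPE_IIA2", 9, seed = 11)
  rec1 <- generate_recording(spec, n_trials = 3L)
  rec2 <- generate_recording(spec, n_trials = 3L)
  expect_identical(rec1, rec2)
  expect_true(all(unlist(rec1$traces) > 0))
  expect_identical(names(rec1$traces[[1]]),
                   c(odor_panel()$odors, "blank"))

  # repeated trials of one odor differ only by noise: their AUCs agree
  # within 3 noise-propagated SDs (weights exposed numerically)
  res <- analyze_neuron(rec1, analysis_config())
  acq <- rec1$acquisition
  tx <- rec1$time_axis
  w <- auc_weights(tx, acq$stimulus_onset)
  n_bl <- sum(tx >= 1 & tx < 2)
  for (g in names(rec1$traces)[1:3]) {
    fit <- fit_bleach(rec1$traces[[g]][["blank"]][[1]], tx)
    aucs <- vapply(1:3, function(tr) {
      corr <- correct_bleach(rec1$traces[[g]][["IA"]][[tr]], fit, tx)
      d <- compute_dff(corr, tx, c(1, 2))
      response_auc(d$dff, tx, acq$stimulus_onset)
    }, 0)
    sigma_dff <- acq$noise_sigma / rec1$baseline
    sd_auc <- sigma_dff * sqrt(sum(w^2) + 9 / n_bl)
    expect_lt(max(aucs) - min(aucs), 2 * 3 * sd_auc)
  }
})

test_that("blank trials carry no stimulus drive", {
  rec <- generate_recording(neuron_spec("TYPE_I", 9, seed = 5))
  tx <- rec$time_axis
  acq <- rec$acquisition
  win <- tx >= acq$stimulus_onset & tx < acq$stimulus_onset + 3
  for (g in names(rec$traces)[1:4]) {
    blank <- rec$traces[[g]][["blank"]][[1]]
    fit <- fit_bleach(blank, tx)
    d <- compute_dff(correct_bleach(blank, fit, tx), tx, c(1, 2))
    bound <- 3 * (acq$noise_sigma / d$f0) / sqrt(sum(win))
    expect_lt(abs(mean(d$dff[win])), bound + 1e-3)
  }
})

test_that("rendered stacks are recoverable by ROI extraction", {
  rec <- generate_recording(neuron_spec("TYPE_I", 9, seed = 2,
                                        noise_sigma = 0))
  # zero pixel noise: extracted traces equal the input exactly
  st0 <- render_stack(rec, 64, 64, rng_seed = 1, pixel_sigma = 0)
  ts0 <- extract_roi_traces(st0)
  expect_equal(ts0$traces[["g01"]][["HX"]][[1]],
               rec$traces[["g01"]][["HX"]][[1]], tolerance = 1e-12)

  # noisy pixels: per-frame ROI means within 3 SEM of the source trace
  st <- render_stack(rec, 64, 64, rng_seed = 1, pixel_sigma = 10)
  n_pix <- sum(st$label_mask == 1L)
  expect_gte(n_pix, 20L)
  ts <- extract_roi_traces(st)
  dev <- ts$traces[["g01"]][["GE"]][[1]] - rec$traces[["g01"]][["GE"]][[1]]
  expect_lt(max(abs(dev)), 3.9 * 10 / sqrt(n_pix))  # ~3 SEM, 180 frames

  # analysing the extracted traces reproduces the in-memory analysis
  expect_equal(analyze_neuron(ts)$summary$mean_r,
               analyze_neuron(rec)$summary$mean_r, tolerance = 0.05)

  expect_error(extract_roi_traces(st$frames, st$label_mask,
                                  required_labels = 99L), "absent")
  expect_error(extract_roi_traces(st$frames, matrix(0L, 64, 64)),
               "no positive labels")
  expect_error(extract_roi_traces(st$frames, matrix(1L, 3, 3)), "match")
  expect_error(render_stack(rec, 12, 12, radius = 4), "place|small")
})
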