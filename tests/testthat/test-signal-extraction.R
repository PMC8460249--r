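test_that("ROI means are plain arithmetic means over mask pixels", {
  fr <- array(7, dim = c(5, 4, 4))
  mask <- matrix(0L, 4, 4); mask[1:2, 1] <- 1L
  tr <- extract_roi_traces(fr, mask)
  expect_equal(as.numeric(tr), rep(7, 5))

  fr[1, 1, 1] <- 10; fr[1, 2, 1] <- 20
  expect_equal(unname(extract_roi_traces(fr, mask)[1, 1]), 15)
})

test_that("bleach fitting recovers a noise-free biexponential blank", {
  acq <- quiet_acq()
  tx <- time_axis(acq)
  f <- 150 * exp(-tx / 8) + 850 * exp(-tx / 200)
  fit <- fit_bleach(f, tx)
  # parameters may trade off on a 10-s window; the curve is the oracle
  expect_lt(max(abs(bleach_curve(fit, tx) - f)), 0.1)
  expect_lt(fit$tau1, fit$tau2)
  expect_true(fit$converged)
})

test_that("bleach fitting handles flat, noisy, and degenerate traces", {
  acq <- quiet_acq()
  tx <- time_axis(acq)

  # constant trace: exact flat fit, correction is the identity
  fit <- fit_bleach(rep(1000, length(tx)), tx)
  expect_true(fit$converged)
  expect_equal(bleach_curve(fit, tx), rep(1000, length(tx)))
  expect_equal(correct_bleach(rep(1000, length(tx)), fit, tx),
               rep(1000, length(tx)))

  # noisy blank: residual RMS at the noise floor
  set.seed(99)
  f <- 150 * exp(-tx / 8) + 850 * exp(-tx / 200) + rnorm(length(tx), 0, 5)
  fitn <- fit_bleach(f, tx)
  expect_lt(sqrt(mean((bleach_curve(fitn, tx) - f)^2)), 1.5 * 5)

  expect_error(fit_bleach(rep(1000, 10), tx[1:10]), "20 frames")
  expect_error(fit_bleach(c(-1, rep(1000, length(tx) - 1)), tx), "positive")
})

test_that("divisive bleach correction flattens the blank and preserves signal", {
  acq <- quiet_acq()
  tx <- time_axis(acq)
  blank <- synthesize_trace(0, acq)
  fit <- fit_bleach(blank, tx)

  # correcting the blank by its own fit gives a flat line at F_hat(0)
  corr <- correct_bleach(blank, fit, tx)
  expect_equal(corr, rep(bleach_curve(fit, 0), length(tx)), tolerance = 1e-3)

  # a bleached odor trace corrects to its bleach-free counterpart
  odor <- synthesize_trace(0.8, acq)
  flat_acq <- acquisition_params(bleach_a1 = 0, bleach_tau1 = 8,
                                 bleach_a2 = 1, bleach_tau2 = 1e9,
                                 noise_sigma = 0)
  free <- synthesize_trace(0.8, flat_acq)
  corr_odor <- correct_bleach(odor, fit, tx)
  expect_lt(max(abs(corr_odor - free)) / max(free), 1e-3)

  # subtractive mode exists and also flattens the blank
  corr_sub <- correct_bleach(blank, fit, tx, mode = "subtract")
  expect_equal(corr_sub, rep(bleach_curve(fit, 0), length(tx)),
               tolerance = 1e-3)
})

test_that("dF/F0 is anchored to the pre-stimulus baseline", {
  acq <- quiet_acq()
  tx <- time_axis(acq)
  expect_equal(compute_dff(rep(500, length(tx)), tx, c(1, 2))$dff,
               rep(0, length(tx)))
  stepped <- ifelse(tx >= 2, 600, 500)
  expect_equal(max(compute_dff(stepped, tx, c(1, 2))$dff), 0.2)
  expect_error(compute_dff(rep(-5, length(tx)), tx, c(1, 2)), "positive")
  expect_error(compute_dff(rep(5, length(tx)), tx, c(1, 1.1)), "5 frames")

  # end to end: the dF/F0 peak equals ground-truth amplitude x sampled
  # kernel peak (noise-free spiking neuron)
  rec <- noisefree_type1()
  g <- "g03"; o <- "IA"
  amp <- rec$ground_truth$response_matrix[g, o]
  fit <- fit_bleach(rec$traces[[g]][["blank"]][[1]], tx)
  d <- compute_dff(correct_bleach(rec$traces[[g]][[o]][[1]], fit, tx),
                   tx, c(1, 2))
  k_peak <- max(glomtune:::response_kernel(tx, 2))
  expect_equal(max(d$dff), amp * k_peak, tolerance = 1e-3)
})

test_that("pipeline response scales linearly with signal above background", {
  acq <- quiet_acq()
  tx <- time_axis(acq)
  blank <- synthesize_trace(0, acq)
  fit <- fit_bleach(blank, tx)
  f1 <- synthesize_trace(0.4, acq)
  f2 <- blank + 2 * (f1 - blank)  # doubled odor-evoked component
  d1 <- compute_dff(correct_bleach(f1, fit, tx), tx, c(1, 2))$dff
  d2 <- compute_dff(correct_bleach(f2, fit, tx), tx, c(1, 2))$dff
  expect_lt(max(abs(d2 - 2 * d1)), 1e-4)
})
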