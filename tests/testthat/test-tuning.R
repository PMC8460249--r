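test_that("response AUC integrates the analysis window exactly", {
  acq <- quiet_acq()
  tx <- time_axis(acq)
  expect_equal(response_auc(rep(0, length(tx)), tx, 2), 0)
  expect_equal(response_auc(rep(0.1, length(tx)), tx, 2), 0.3)

  # linear ramp 0 -> 0.2 across the window: closed-form integral is 0.3
  ramp <- pmin(pmax((tx - 2) / 3, 0), 1) * 0.2
  expect_equal(response_auc(ramp, tx, 2), 0.3, tolerance = 1e-3)

  expect_error(response_auc(rep(0, length(tx)), tx, 8, window = 3),
               "not covered")
})

test_that("tuning curves normalise to the glomerulus maximum", {
  tc <- build_tuning_curve(c(A = 2, B = 4, C = 1), blank_auc = 0.05)
  expect_equal(tc$normalized, c(A = 0.5, B = 1, C = 0.25))
  expect_identical(tc$max_odor, "B")
  expect_false(tc$tie_flag)
  expect_equal(tc$blank_auc, 0.05)

  tie <- build_tuning_curve(c(A = 3, B = 3))
  expect_equal(unname(tie$normalized), c(1, 1))
  expect_true(tie$tie_flag)
  expect_identical(tie$max_odor, "A")  # first in panel order

  neg <- build_tuning_curve(c(A = -1, B = 2))
  expect_equal(neg$normalized, c(A = -0.5, B = 1))

  dead <- build_tuning_curve(c(A = -1, B = -2))
  expect_true(dead$non_responsive)

  # scale invariance: a positive gain leaves the normalised curve unchanged
  a <- c(A = 0.3, B = 1.1, C = 0.7, D = -0.2)
  expect_equal(build_tuning_curve(a)$normalized,
               build_tuning_curve(5.7 * a)$normalized)
})

test_that("noise-free spiking neurons share one preferred odor", {
  rec <- noisefree_type1(seed = 4, n_gl = 10L)
  res <- analyze_neuron(rec)
  maxes <- vapply(res$curves, function(tc) tc$max_odor, "")
  expect_length(unique(maxes), 1L)
  expect_identical(unique(maxes),
                   rec$panel$odors[which.max(rec$ground_truth$shared_tuning)])
})
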