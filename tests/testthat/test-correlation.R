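test_that("spearman_r matches hand-derived values and handles ties", {
  expect_equal(spearman_r(1:3, 1:3), 1)
  expect_equal(spearman_r(1:3, 3:1), -1)
  # rank y with average ties: (1, 2, 3.5, 5, 3.5); Pearson on ranks by hand
  expect_equal(spearman_r(1:5, c(5, 6, 7, 8, 7)), 8 / sqrt(95))
  # agrees with the reference implementation under ties
  set.seed(3)
  for (i in 1:20) {
    x <- sample(1:5, 9, replace = TRUE); y <- sample(1:5, 9, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(spearman_r(x, y), cor(x, y, method = "spearman"))
  }
  expect_true(is.na(spearman_r(rep(1, 5), 1:5)))
  expect_error(spearman_r(1:4, 1:5), "equal length")
})

test_that("spearman_r is invariant under strictly monotone transforms", {
  set.seed(11)
  for (i in 1:20) {
    x <- runif(9); y <- runif(9)
    r <- spearman_r(x, y)
    expect_equal(spearman_r(exp(3 * x), y), r)
    expect_equal(spearman_r(x, y^3 + 2 * y), r)
  }
})

test_that("correlation matrices are symmetric with unit diagonal", {
  m <- rbind(c(0.1, 0.5, 1.0, 0.3), c(0.2, 0.6, 1.0, 0.4),
             c(1.0, 0.5, 0.1, 0.8))
  cm <- correlation_matrix(m)
  expect_equal(cm$r, t(cm$r))
  expect_equal(diag(cm$r), rep(1, 3), ignore_attr = TRUE)
  expect_true(all(cm$r >= -1 & cm$r <= 1))

  # hand-built rank patterns: identity, reversal, identity
  pat <- rbind(1:5, 5:1, c(10, 20, 30, 40, 50))
  expect_equal(unname(correlation_matrix(pat)$r),
               rbind(c(1, -1, 1), c(-1, 1, -1), c(1, -1, 1)))

  # identical curves -> all-ones matrix; also forced for noise-free TYPE_I
  same <- matrix(rep(c(0.2, 1, 0.6), 4), 4, 3, byrow = TRUE)
  expect_true(all(correlation_matrix(same)$r == 1))
  res <- analyze_neuron(noisefree_type1())
  expect_true(all(res$matrix$r == 1))

  # non-responsive glomeruli are excluded but reported
  curves <- list(build_tuning_curve(c(A = 1, B = 2, C = 3), glomerulus = "g1"),
                 build_tuning_curve(c(A = -1, B = -2, C = -3), glomerulus = "g2"),
                 build_tuning_curve(c(A = 2, B = 1, C = 3), glomerulus = "g3"))
  cm2 <- correlation_matrix(curves)
  expect_identical(cm2$excluded, "g2")
  expect_identical(cm2$glomeruli, c("g1", "g3"))
  expect_error(correlation_matrix(curves[1:2]), "at least 2")
})

test_that("summaries use raw upper-triangle coefficients", {
  r <- diag(1, 3)
  r[1, 2] <- r[2, 1] <- 0.2
  r[1, 3] <- r[3, 1] <- 0.4
  r[2, 3] <- r[3, 2] <- 0.6
  cm <- structure(list(r = r, glomeruli = letters[1:3], n_odors_used = 9,
                       excluded = character(0)),
                  class = "correlation_matrix")
  s <- summarize_correlations(cm)
  expect_equal(c(s$mean_r, s$median_r, s$min_r, s$max_r),
               c(0.4, 0.4, 0.2, 0.6))
  expect_true(s$min_r <= s$median_r && s$median_r <= s$max_r)

  # permutation invariance of the summary
  perm <- c(3, 1, 2)
  cmp <- cm; cmp$r <- r[perm, perm]; cmp$glomeruli <- cm$glomeruli[perm]
  sp <- summarize_correlations(cmp)
  expect_equal(sp$mean_r, s$mean_r)
  expect_equal(sp$median_r, s$median_r)

  # 2x2 case: all statistics collapse to the single coefficient
  cm2 <- correlation_matrix(rbind(c(1, 2, 4), c(1, 4, 2)))
  s2 <- summarize_correlations(cm2)
  expect_equal(c(s2$mean_r, s2$median_r, s2$min_r, s2$max_r),
               rep(0.5, 4))

  # undefined pairs are dropped with a warning, not zeroed
  cmu <- cm; cmu$r[1, 2] <- cmu$r[2, 1] <- NA
  expect_warning(su <- summarize_correlations(cmu), "undefined")
  expect_equal(su$mean_r, 0.5)
  expect_equal(su$n_undefined_pairs, 1L)
})

test_that("heatmap clipping is display-only", {
  cm <- correlation_matrix(rbind(1:5, 5:1, 1:5))
  hm <- heatmap_matrix(cm)
  expect_equal(unname(hm$r), rbind(c(1, 0, 1), c(0, 1, 0), c(1, 0, 1)))
  # the original matrix and its summary are untouched
  expect_equal(cm$r[1, 2], -1)
  expect_equal(summarize_correlations(cm)$mean_r, (-1 - 1 + 1) / 3)
})
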