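test_that("Kruskal-Wallis H matches the rank-sum formula", {
  # by hand: ranks 1..6, R1 = 6, R2 = 15, H = 12/42 * (12 + 75) - 21 = 27/7
  out <- kruskal_wallis(list(a = 1:3, b = 4:6))
  expect_equal(out$H, 27 / 7)
  expect_equal(round(out$H, 3), 3.857)
  expect_equal(out$df, 1L)
  expect_equal(out$p, pchisq(27 / 7, 1, lower.tail = FALSE))

  same <- kruskal_wallis(list(a = c(2, 2, 2), b = c(2, 2, 2)))
  expect_equal(same$H, 0)
  expect_equal(same$p, 1)

  expect_error(kruskal_wallis(list(a = numeric(0), b = 1:5)), "empty")
  expect_error(kruskal_wallis(list(a = 1, b = 2)), "at least 5")
})

test_that("Kruskal-Wallis is rank-based and label-symmetric", {
  g <- list(a = c(0.1, 0.9, 0.4, 0.7), b = c(0.2, 0.8, 0.3),
            c = c(0.5, 0.6, 0.95))
  h0 <- kruskal_wallis(g)$H
  mono <- lapply(g, function(v) exp(5 * v) - 1)   # strictly increasing map
  expect_equal(kruskal_wallis(mono)$H, h0)
  expect_equal(kruskal_wallis(g[c(3, 1, 2)])$H, h0)
})

test_that("Dunn post hoc follows the pooled-rank z formula", {
  # rank means 2 and 5, N = 6, no ties:
  # z = (2 - 5)/sqrt((6*7/12) * (1/3 + 1/3)) = -3/sqrt(7/3)
  dn <- dunn_posthoc(list(a = 1:3, b = 4:6))
  expect_equal(dn$z, -3 / sqrt(7 / 3))
  expect_equal(round(abs(dn$z), 3), 1.964)
  expect_equal(dn$p_adjusted, dn$p_unadjusted)  # single comparison

  ident <- dunn_posthoc(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(ident$z, 0)
  expect_equal(ident$p_adjusted, 1)

  # Bonferroni-style adjustment is monotone in the number of comparisons
  g3 <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(2, 3, 4))
  one <- dunn_posthoc(g3, comparisons = list(c("a", "b")))
  three <- dunn_posthoc(g3)
  expect_gte(three$p_adjusted[three$group_a == "a" & three$group_b == "b"],
             one$p_adjusted)
  expect_true(all(three$p_adjusted <= 1))

  holm <- dunn_posthoc(g3, method = "holm")
  expect_true(all(holm$p_adjusted <= three$p_adjusted + 1e-12))

  expect_error(dunn_posthoc(g3, comparisons = list(c("a", "z"))), "unknown")
})

test_that("box statistics use type-7 quartiles and Tukey whiskers", {
  b <- box_stats(1:7)
  expect_equal(b$median, 4)
  expect_equal(b$q1, 2.5)
  expect_equal(b$q3, 5.5)
  expect_equal(b$whisker_low, 1)
  expect_equal(b$whisker_high, 7)
  expect_length(b$outliers, 0L)

  flat <- box_stats(rep(3, 5))
  expect_equal(c(flat$q1, flat$median, flat$q3,
                 flat$whisker_low, flat$whisker_high), rep(3, 5))

  # q3 = 4, IQR = 2, upper fence 7 -> 100 is an outlier
  out <- box_stats(c(1, 2, 3, 4, 100))
  expect_equal(out$outliers, 100)
  expect_equal(out$whisker_high, 4)
  expect_true(b$whisker_low <= b$q1 && b$q3 <= b$whisker_high)
})

test_that("compare_groups assembles omnibus, post hoc and box summaries", {
  g <- list(ctrl = c(0.9, 0.95, 0.92, 0.97, 0.96),
            hyp = c(0.5, 0.7, 0.6, 0.75),
            qx = c(0.55, 0.65, 0.7))
  out <- compare_groups(g, comparisons = list(c("ctrl", "hyp"),
                                              c("ctrl", "qx")))
  expect_named(out, c("omnibus", "pairwise", "box", "n"))
  expect_equal(out$omnibus$df, 2L)
  expect_equal(nrow(out$pairwise), 2L)
  expect_equal(out$n, c(ctrl = 5L, hyp = 4L, qx = 3L))
})
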