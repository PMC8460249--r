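#' Kruskal-Wallis rank-sum test across groups of per-neuron statistics
#'
#' Nonparametric omnibus comparison of two or more groups (e.g. per-neuron
#' mean correlation coefficients for control vs. manipulated cells).  The
#' tie-corrected H statistic is referred to a chi-square distribution with
#' k - 1 degrees of freedom.  Delegates to [stats::kruskal.test()].
#'
#' @param groups named list of numeric vectors, one per group.
#' @return A list with `H`, `df`, `p`.
#' @examples
#' kruskal_wallis(list(a = 1:3, b = 4:6))$H   # 3.857
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(vapply(groups, length, 1L) == 0L)) stop("empty group")
  if (sum(lengths(groups)) < 5L) stop("need a total of at least 5 values")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  if (diff(range(x)) == 0) {
    return(list(H = 0, df = length(groups) - 1L, p = 1))
  }
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = unname(kt$p.value))
}

#' Dunn's post hoc pairwise comparisons after Kruskal-Wallis
#'
#' For each requested pair (a, b) of groups, computes
#' \deqn{z = \frac{\bar R_a - \bar R_b}{\sqrt{\left(\frac{N(N+1)}{12} -
#'   \frac{\sum (t^3 - t)}{12 (N - 1)}\right)
#'   \left(\frac{1}{n_a} + \frac{1}{n_b}\right)}},}
#' where \eqn{\bar R} are mean ranks over the pooled sample of size \eqn{N}
#' and the tie term sums over tied-value groups of size \eqn{t}.  Two-sided
#' p values from the standard normal are adjusted for multiplicity by
#' multiplication with the number of requested comparisons (Bonferroni-style
#' Dunn adjustment, capped at 1); Holm ordering is available via `method`.
#'
#' @param groups named list of numeric vectors.
#' @param comparisons list of length-2 character vectors naming group
#'   pairs; default all pairs.
#' @param method multiplicity adjustment: `"bonferroni"` (classic Dunn) or
#'   `"holm"`.
#' @return data.frame with columns group_a, group_b, z, p_unadjusted,
#'   p_adjusted, plus attribute `n_comparisons`.
#' @examples
#' dunn_posthoc(list(a = 1:3, b = 4:6))
#' @export
dunn_posthoc <- function(groups, comparisons = NULL,
                         method = c("bonferroni", "holm")) {
  method <- match.arg(method)
  stopifnot(is.list(groups), length(groups) >= 2L,
            !is.null(names(groups)))
  if (is.null(comparisons)) {
    nm <- names(groups)
    comparisons <- list()
    for (i in seq_along(nm)[-length(nm)])
      for (j in (i + 1L):length(nm))
        comparisons[[length(comparisons) + 1L]] <- c(nm[i], nm[j])
  }
  for (cp in comparisons)
    if (!all(cp %in% names(groups)))
      stop("unknown group in comparison: ", paste(cp, collapse = " vs "))

  x <- unlist(groups, use.names = FALSE)
  gl <- rep(names(groups), lengths(groups))
  N <- length(x)
  rk <- rank(x)
  tie_sizes <- table(x)
  tie_term <- sum(tie_sizes^3 - tie_sizes) / (12 * (N - 1))
  var_term <- N * (N + 1) / 12 - tie_term
  rbar <- tapply(rk, gl, mean)
  n_by <- tapply(rk, gl, length)

  res <- do.call(rbind, lapply(comparisons, function(cp) {
    a <- cp[1]; b <- cp[2]
    se <- sqrt(var_term * (1 / n_by[[a]] + 1 / n_by[[b]]))
    z <- if (se == 0) 0 else (rbar[[a]] - rbar[[b]]) / se
    data.frame(group_a = a, group_b = b, z = z,
               p_unadjusted = 2 * pnorm(-abs(z)), row.names = NULL)
  }))
  m <- length(comparisons)
  res$p_adjusted <- if (method == "bonferroni") {
    pmin(res$p_unadjusted * m, 1)
  } else {
    stats::p.adjust(res$p_unadjusted, method = "holm")
  }
  attr(res, "n_comparisons") <- m
  res
}

#' Box-plot statistics with Tukey whiskers
#'
#' Quartiles by linear interpolation of order statistics
#' ([stats::quantile()] type 7); whiskers extend to the most extreme data
#' points within 1.5 interquartile ranges of the box; points beyond are
#' listed as outliers.
#'
#' @param values numeric vector, length >= 3.
#' @return A list with `median`, `q1`, `q3`, `whisker_low`, `whisker_high`,
#'   `outliers`, `n`.
#' @examples
#' box_stats(1:7)          # box 2.5-5.5, no outliers
#' box_stats(c(1, 2, 3, 4, 100))$outliers   # 100
#' @export
box_stats <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 3L, all(is.finite(values)))
  q <- quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values >= lo_fence & values <= hi_fence
  list(median = q[2], q1 = q[1], q3 = q[3],
       whisker_low = min(values[inside]),
       whisker_high = max(values[inside]),
       outliers = sort(values[!inside]),
       n = length(values))
}

#' Compare per-neuron mean correlations across groups
#'
#' Convenience wrapper running the omnibus Kruskal-Wallis test, Dunn post
#' hoc comparisons, and per-group box statistics on a named list of
#' per-neuron values.
#'
#' @param groups named list of numeric vectors (one value per neuron).
#' @param comparisons passed to [dunn_posthoc()]; default all pairs.
#' @param method multiplicity adjustment for the post hoc tests.
#' @return A list with `omnibus` (H, df, p), `pairwise` (data frame),
#'   `box` (per-group [box_stats()]), `n` (per-group sizes).
#' @export
compare_groups <- function(groups, comparisons = NULL,
                           method = c("bonferroni", "holm")) {
  method <- match.arg(method)
  omnibus <- kruskal_wallis(groups)
  pairwise <- dunn_posthoc(groups, comparisons, method)
  list(omnibus = omnibus, pairwise = pairwise,
       box = lapply(groups, box_stats),
       n = lengths(groups))
}
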