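#' Spearman rank correlation of two tuning vectors
#'
#' Pearson correlation of the average-tie ranks of `x` and `y` — the
#' standard Spearman coefficient with fractional ranks for ties (ties are
#' common in 9-point tuning curves).  If either vector is constant the
#' coefficient is undefined and `NA` is returned.
#'
#' @param x,y numeric vectors of equal length >= 3, finite.
#' @return Correlation in `[-1, 1]`, or `NA` if undefined.
#' @examples
#' spearman_r(1:3, 3:1)                      # -1
#' spearman_r(1:5, c(5, 6, 7, 8, 7))          # 0.8207
#' @export
spearman_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values")
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) return(NA_real_)
  cor(rx, ry)
}

#' Pairwise Spearman correlation matrix of glomerular tuning curves
#'
#' Correlates the normalised tuning curves of every pair of responsive
#' glomeruli within a neuron.  Non-responsive glomeruli (no positive AUC)
#' are excluded and listed in the result.
#'
#' @param curves list of [build_tuning_curve()] objects sharing one odor
#'   panel, or a numeric matrix (glomeruli in rows, odors in columns).
#' @return An object of class `correlation_matrix`: `r` (symmetric, unit
#'   diagonal), `glomeruli`, `n_odors_used`, `excluded` (labels of
#'   non-responsive glomeruli).
#' @export
correlation_matrix <- function(curves) {
  if (is.matrix(curves)) {
    mat <- curves
    if (is.null(rownames(mat))) rownames(mat) <- sprintf("g%02d", seq_len(nrow(mat)))
    excluded <- character(0)
  } else {
    resp <- vapply(curves, function(tc) !tc$non_responsive, TRUE)
    excluded <- vapply(curves[!resp], function(tc) tc$glomerulus, "")
    curves <- curves[resp]
    if (length(curves) >= 1L) {
      panels <- vapply(curves, function(tc) paste(names(tc$normalized),
                                                  collapse = "\r"), "")
      if (length(unique(panels)) != 1L)
        stop("all tuning curves must share one odor panel")
    }
    mat <- do.call(rbind, lapply(curves, function(tc) tc$normalized))
    rownames(mat) <- vapply(curves, function(tc) tc$glomerulus, "")
  }
  if (nrow(mat) < 2L)
    stop("need at least 2 responsive glomeruli (",
         length(excluded), " excluded)")
  n <- nrow(mat)
  r <- diag(1, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    r[i, j] <- r[j, i] <- spearman_r(mat[i, ], mat[j, ])
  }
  dimnames(r) <- list(rownames(mat), rownames(mat))
  structure(list(r = r, glomeruli = rownames(mat),
                 n_odors_used = ncol(mat), excluded = excluded),
            class = "correlation_matrix")
}

#' Summarise a within-neuron correlation matrix
#'
#' Statistics of the \eqn{n(n-1)/2} upper-triangle off-diagonal
#' coefficients, on the raw (unclipped) scale.  Undefined (NA) coefficients
#' — produced by constant tuning vectors — are excluded and counted, not
#' treated as zero.
#'
#' @param matrix a `correlation_matrix`.
#' @param neuron_id,cell_type labels carried into the summary.
#' @return An object of class `correlation_summary`: `neuron_id`,
#'   `cell_type`, `n_glomeruli`, `mean_r`, `median_r`, `min_r`, `max_r`,
#'   `n_pairs`, `n_undefined_pairs`.
#' @examples
#' m <- correlation_matrix(rbind(c(1, 2, 3), c(1, 2, 3), c(3, 2, 1)))
#' summarize_correlations(m)$mean_r   # (1 - 1 - 1)/3
#' @export
summarize_correlations <- function(matrix, neuron_id = "neuron",
                                   cell_type = NA_character_) {
  stopifnot(inherits(matrix, "correlation_matrix"))
  r <- matrix$r
  if (nrow(r) < 2L) stop("matrix must be at least 2x2")
  off <- r[upper.tri(r)]
  n_undef <- sum(is.na(off))
  off <- off[!is.na(off)]
  if (length(off) == 0L) stop("all pairwise coefficients are undefined")
  if (n_undef > 0L)
    warning(n_undef, " undefined pairwise coefficient(s) excluded")
  structure(list(neuron_id = neuron_id, cell_type = cell_type,
                 n_glomeruli = nrow(r),
                 mean_r = mean(off), median_r = median(off),
                 min_r = min(off), max_r = max(off),
                 n_pairs = length(off), n_undefined_pairs = n_undef),
            class = "correlation_summary")
}

#' @export
print.correlation_summary <- function(x, ...) {
  cat(sprintf("<correlation_summary> %s (%s): %d glomeruli, mean r=%.3f, median=%.3f, range=[%.3f, %.3f]\n",
              x$neuron_id, x$cell_type, x$n_glomeruli, x$mean_r,
              x$median_r, x$min_r, x$max_r))
  invisible(x)
}

#' Clip a correlation matrix for heatmap display
#'
#' Negative coefficients are set to zero — a display convention only; all
#' summary statistics are computed on the raw matrix.
#'
#' @param matrix a `correlation_matrix`.
#' @return A `correlation_matrix` with `r` clipped at zero element-wise.
#' @export
heatmap_matrix <- function(matrix) {
  stopifnot(inherits(matrix, "correlation_matrix"))
  matrix$r <- pmax(matrix$r, 0)
  matrix
}

#' Correlation summaries as a data frame
#'
#' @param summaries list of `correlation_summary` objects.
#' @return data.frame, one row per neuron.
#' @export
summary_table <- function(summaries) {
  do.call(rbind, lapply(summaries, function(s)
    data.frame(neuron_id = s$neuron_id, cell_type = s$cell_type,
               n_glomeruli = s$n_glomeruli, mean_r = s$mean_r,
               median_r = s$median_r, min_r = s$min_r, max_r = s$max_r,
               n_pairs = s$n_pairs,
               n_undefined_pairs = s$n_undefined_pairs,
               row.names = NULL)))
}
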