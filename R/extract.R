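#' Container for per-ROI fluorescence traces
#'
#' Holds uniformly sampled fluorescence series per (glomerulus, stimulus,
#' trial), with the trial time axis and acquisition metadata.  This is the
#' common input of the analysis pipeline, produced either by
#' [extract_roi_traces()] from an image stack, by [read_traces_csv()], or
#' directly from a [generate_recording()] result via [as_roi_trace_set()].
#'
#' @param traces nested list `[[glomerulus]][[stimulus]][[trial]]` of equal
#'   length numeric vectors.
#' @param time_axis frame times (s), shared by all traces.
#' @param acquisition an [acquisition_params()] or `NULL`.
#' @param panel an [odor_panel()] describing which stimulus is the blank.
#' @param neuron_id,cell_type labels.
#' @return An object of class `roi_trace_set`.
#' @export
roi_trace_set <- function(traces, time_axis, acquisition = NULL,
                          panel = odor_panel(), neuron_id = "neuron",
                          cell_type = NA_character_) {
  lens <- unlist(lapply(traces, function(g)
    lapply(g, function(s) vapply(s, length, 1L))))
  if (length(unique(lens)) != 1L)
    stop("all traces must have equal length")
  if (unique(lens) != length(time_axis))
    stop("trace length does not match time axis")
  structure(list(traces = traces, time_axis = time_axis,
                 acquisition = acquisition, panel = panel,
                 neuron_id = neuron_id, cell_type = cell_type),
            class = "roi_trace_set")
}

#' Coerce a simulated recording to a ROI trace set
#'
#' @param recording a `simulated_recording`.
#' @return A `roi_trace_set` sharing the recording's traces and metadata.
#' @export
as_roi_trace_set <- function(recording) {
  stopifnot(inherits(recording, "simulated_recording"))
  roi_trace_set(recording$traces, recording$time_axis,
                acquisition = recording$acquisition,
                panel = recording$panel,
                neuron_id = recording$neuron_id,
                cell_type = recording$spec$cell_type)
}

#' Fit the biexponential photobleaching model to a blank-trial trace
#'
#' Fits \eqn{\hat F(t) = a_1 e^{-t/\tau_1} + a_2 e^{-t/\tau_2} + c} by
#' Levenberg-Marquardt nonlinear least squares.  The blank (mineral-oil)
#' trial lacks odor-evoked calcium influx, so its time course isolates the
#' bleaching decay.  Initialisation: `c = min(F)`,
#' `a1 = a2 = (F[1] - c)/2`, with a short ladder of `(tau1, tau2)` starts
#' anchored at `(span/10, 2*span)` (biexponential least squares is
#' multimodal when the time constants are poorly separated; the best
#' residual wins).  Bounds keep amplitudes non-negative and `tau1` within
#' `[2*frame_interval, span]`, `tau2` within `[2*frame_interval,
#' 100*span]`.  Components are relabelled
#' so `tau1 < tau2`.  If the biexponential fit fails to converge, a
#' monoexponential is fitted instead and `converged` is set `FALSE`.  A
#' constant trace short-circuits to the exact flat fit.
#'
#' @param blank_trace fluorescence series (AU), all values > 0.
#' @param time_axis frame times (s), same length.
#' @return An object of class `bleach_fit` with fields `a1`, `tau1`, `a2`,
#'   `tau2`, `c`, `rss`, `converged`.
#' @examples
#' acq <- acquisition_params(noise_sigma = 0)
#' f <- synthesize_trace(0, acq)
#' fit <- fit_bleach(f, time_axis(acq))
#' stopifnot(fit$converged)
#' @export
fit_bleach <- function(blank_trace, time_axis) {
  if (length(blank_trace) < 20L) stop("need at least 20 frames")
  if (length(blank_trace) != length(time_axis))
    stop("trace and time axis lengths differ")
  if (any(blank_trace <= 0)) stop("blank trace must be positive")
  F <- as.numeric(blank_trace); t <- as.numeric(time_axis)
  span <- diff(range(t))
  dt <- t[2] - t[1]

  new_fit <- function(a1, tau1, a2, tau2, c, rss, converged) {
    if (tau1 > tau2) { tmp <- a1; a1 <- a2; a2 <- tmp
                       tmp <- tau1; tau1 <- tau2; tau2 <- tmp }
    structure(list(a1 = a1, tau1 = tau1, a2 = a2, tau2 = tau2, c = c,
                   rss = rss, converged = converged),
              class = "bleach_fit")
  }

  # flat trace: exact degenerate fit, no decay to estimate
  if (diff(range(F)) < 1e-9 * max(abs(F))) {
    return(new_fit(0, span / 10, 0, 2 * span, mean(F), 0, TRUE))
  }

  c0 <- min(F); amp0 <- max((F[1] - c0) / 2, 1e-6)
  ctrl <- minpack.lm::nls.lm.control(maxiter = 300, maxfev = 20000,
                                     ftol = 1e-10, ptol = 1e-10)
  lm_fit <- function(par, lower, upper, resid_fn) {
    out <- tryCatch(suppressWarnings(
      minpack.lm::nls.lm(par = par, fn = resid_fn, lower = lower,
                         upper = upper, control = ctrl)),
                    error = function(e) NULL)
    if (is.null(out) || !is.finite(out$deviance)) return(NULL)
    out
  }
  biexp_resid <- function(p) F - (p[1] * exp(-t / p[3]) +
                                  p[2] * exp(-t / p[4]) + p[5])
  # biexponential least squares is multimodal when the two time constants
  # are poorly separated; run a short ladder of tau starts and keep the
  # best, stopping early once the residual reaches the noise floor
  sigma_hat <- stats::mad(diff(F, differences = 2)) / sqrt(6)
  good_rmse <- max(1.5 * sigma_hat, 1e-4 * diff(range(F)))
  starts <- list(c(span / 10, 2 * span), c(span / 20, span),
                 c(span / 5, 5 * span), c(span / 3, 10 * span),
                 c(2.5 * dt, 5 * span))
  best <- NULL
  for (s in starts) {
    out <- lm_fit(c(amp0, amp0, s[1], s[2], c0),
                  lower = c(0, 0, 2 * dt, 2 * dt, 0),
                  upper = c(Inf, Inf, span, 100 * span, Inf),
                  biexp_resid)
    if (is.null(out)) next
    if (is.null(best) || out$deviance < best$deviance) best <- out
    if (sqrt(best$deviance / length(F)) <= good_rmse) break
  }
  # the LM info code is unreliable on the flat valleys of ill-conditioned
  # biexponentials; judge convergence by the achieved residual as well
  if (!is.null(best)) {
    rmse <- sqrt(best$deviance / length(F))
    if (best$info %in% 1:4 || rmse <= max(good_rmse, 2.5 * sigma_hat)) {
      p <- best$par
      return(new_fit(p[1], p[3], p[2], p[4], p[5], best$deviance, TRUE))
    }
  }
  # fallback: monoexponential, flagged unconverged
  out1 <- lm_fit(c(2 * amp0, span / 2, c0),
                 lower = c(0, 2 * dt, 0), upper = c(Inf, 100 * span, Inf),
                 function(p) F - (p[1] * exp(-t / p[2]) + p[3]))
  if (!is.null(out1)) {
    p <- out1$par
    return(new_fit(p[1], p[2], 0, 100 * span, p[3], out1$deviance, FALSE))
  }
  new_fit(0, span / 10, 0, 2 * span, mean(F),
          sum((F - mean(F))^2), FALSE)
}

#' Evaluate a bleach fit
#'
#' @param fit a `bleach_fit`.
#' @param t time in seconds.
#' @return Fitted fluorescence \eqn{\hat F(t)}.
#' @export
bleach_curve <- function(fit, t) {
  fit$a1 * exp(-t / fit$tau1) + fit$a2 * exp(-t / fit$tau2) + fit$c
}

#' @export
print.bleach_fit <- function(x, ...) {
  cat(sprintf("<bleach_fit> a1=%.3g tau1=%.3g a2=%.3g tau2=%.3g c=%.3g rss=%.3g%s\n",
              x$a1, x$tau1, x$a2, x$tau2, x$c, x$rss,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Correct a fluorescence trace for photobleaching
#'
#' Bleaching is multiplicative photophysics, so the default correction is
#' divisive: \eqn{F_{corr}(t) = F(t) / (\hat F(t) / \hat F(0))}, i.e. the
#' trace is divided by the fitted decay normalised to its value at
#' \eqn{t = 0}.  A subtractive mode
#' (\eqn{F_{corr}(t) = F(t) - \hat F(t) + \hat F(0)}) is available for
#' comparison.
#'
#' @param trace fluorescence series (AU).
#' @param fit a `bleach_fit` from the same glomerulus's blank trial.
#' @param time_axis frame times (s).
#' @param mode `"divide"` (default) or `"subtract"`.
#' @return Corrected fluorescence series.
#' @export
correct_bleach <- function(trace, fit, time_axis,
                           mode = c("divide", "subtract")) {
  mode <- match.arg(mode)
  fhat <- bleach_curve(fit, time_axis)
  if (any(fhat <= 0)) stop("fitted bleach curve must be positive")
  f0 <- bleach_curve(fit, 0)
  if (mode == "divide") trace / (fhat / f0) else trace - fhat + f0
}

#' Compute relative fluorescence change dF/F0
#'
#' \eqn{F_0} is the mean of the corrected trace over a pre-stimulus baseline
#' window (default: the second immediately preceding stimulus onset);
#' \eqn{\Delta F/F_0(t) = (F_{corr}(t) - F_0)/F_0}.
#'
#' @param corrected bleach-corrected fluorescence series.
#' @param time_axis frame times (s).
#' @param baseline_window numeric length-2 vector `[start, end)` in seconds;
#'   must contain at least 5 frames and end at or before stimulus onset.
#' @return A list with `dff` (series) and `f0` (scalar, AU).
#' @examples
#' acq <- acquisition_params()
#' tx <- time_axis(acq)
#' out <- compute_dff(rep(500, length(tx)), tx, c(1, 2))
#' stopifnot(all(out$dff == 0), out$f0 == 500)
#' @export
compute_dff <- function(corrected, time_axis, baseline_window) {
  stopifnot(length(baseline_window) == 2L,
            baseline_window[1] < baseline_window[2])
  idx <- time_axis >= baseline_window[1] & time_axis < baseline_window[2]
  if (sum(idx) < 5L) stop("baseline window must contain at least 5 frames")
  f0 <- mean(corrected[idx])
  if (f0 <= 0) stop("baseline fluorescence F0 must be positive")
  list(dff = (corrected - f0) / f0, f0 = f0)
}
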