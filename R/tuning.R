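#' Response magnitude: area under the dF/F0 curve after stimulus onset
#'
#' Trapezoidal integral of the dF/F0 series over the analysis window
#' `[onset, onset + window)` (default 3 s, the interval over which the
#' odor-evoked transient is quantified).  The window edges are included by
#' linear interpolation so the integral always spans exactly `window`
#' seconds; a constant dF/F0 of 0.1 therefore yields 0.3 (dF/F0)·s for the
#' default window.  Negative values (inhibition-dominated responses) are
#' integrated as-is, so the AUC may be negative.
#'
#' @param dff dF/F0 series (dimensionless).
#' @param time_axis frame times (s).
#' @param onset stimulus onset (s).
#' @param window analysis window length (s), default 3.
#' @return AUC in (dF/F0)·s.
#' @examples
#' acq <- acquisition_params()
#' tx <- time_axis(acq)
#' response_auc(rep(0.1, length(tx)), tx, onset = 2)  # 0.3
#' @export
response_auc <- function(dff, time_axis, onset, window = 3) {
  stopifnot(window > 0, length(dff) == length(time_axis))
  dt <- time_axis[2] - time_axis[1]
  if (onset < time_axis[1] - dt / 2 ||
      onset + window > time_axis[length(time_axis)] + dt / 2)
    stop("analysis window [", onset, ", ", onset + window,
         ") not covered by the trace")
  inside <- time_axis >= onset & time_axis < onset + window
  tt <- c(onset, time_axis[inside], onset + window)
  vv <- c(approx(time_axis, dff, onset, rule = 2)$y,
          dff[inside],
          approx(time_axis, dff, onset + window, rule = 2)$y)
  keep <- !duplicated(tt)
  pracma::trapz(tt[keep], vv[keep])
}

#' Build a per-glomerulus odor tuning curve
#'
#' Normalises the vector of per-odor response AUCs of one glomerulus to its
#' maximum, so the strongest odor response equals 1.  The blank-control AUC
#' is carried along for reporting but excluded from both the curve and the
#' maximum.  Negative AUCs are retained (they normalise to negative values).
#' If no odor elicits a positive AUC the glomerulus is flagged
#' non-responsive; such curves are excluded from correlation analysis
#' downstream (with a record), never silently dropped.
#'
#' @param aucs named numeric vector of per-odor AUCs, names in panel order.
#' @param blank_auc AUC of the blank trial.
#' @param glomerulus label.
#' @return An object of class `tuning_curve` with fields `glomerulus`,
#'   `raw_auc`, `normalized`, `max_odor`, `blank_auc`, `tie_flag`,
#'   `non_responsive`.
#' @examples
#' tc <- build_tuning_curve(c(A = 2, B = 4, C = 1), blank_auc = 0.01)
#' tc$normalized        # 0.5 1.0 0.25
#' tc$max_odor          # "B"
#' @export
build_tuning_curve <- function(aucs, blank_auc = NA_real_,
                               glomerulus = "g") {
  if (length(aucs) < 2L) stop("need at least 2 odors")
  if (is.null(names(aucs)) || anyNA(names(aucs)))
    stop("aucs must be named by odor")
  if (any(!is.finite(aucs))) stop("non-finite AUC")
  mx <- max(aucs)
  non_resp <- mx <= 0
  normalized <- if (non_resp) rep(NA_real_, length(aucs)) else aucs / mx
  names(normalized) <- names(aucs)
  at_max <- which(aucs == mx)
  structure(list(glomerulus = glomerulus,
                 raw_auc = aucs,
                 normalized = normalized,
                 max_odor = names(aucs)[at_max[1]],
                 blank_auc = blank_auc,
                 tie_flag = length(at_max) > 1L,
                 non_responsive = non_resp),
            class = "tuning_curve")
}

#' @export
print.tuning_curve <- function(x, ...) {
  cat(sprintf("<tuning_curve> %s | max: %s%s%s\n", x$glomerulus, x$max_odor,
              if (x$tie_flag) " (tied)" else "",
              if (x$non_responsive) " [non-responsive]" else ""))
  print(round(x$normalized, 3))
  invisible(x)
}

#' Tuning curves as a long data frame
#'
#' @param curves list of `tuning_curve` objects.
#' @param neuron_id label added as a column.
#' @return data.frame with columns neuron_id, glomerulus, odor, raw_auc,
#'   normalized, is_max, blank_auc, non_responsive.
#' @export
tuning_table <- function(curves, neuron_id = "neuron") {
  do.call(rbind, lapply(curves, function(tc)
    data.frame(neuron_id = neuron_id,
               glomerulus = tc$glomerulus,
               odor = names(tc$raw_auc),
               raw_auc = as.numeric(tc$raw_auc),
               normalized = as.numeric(tc$normalized),
               is_max = names(tc$raw_auc) == tc$max_odor & !tc$non_responsive,
               blank_auc = tc$blank_auc,
               non_responsive = tc$non_responsive,
               row.names = NULL)))
}
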