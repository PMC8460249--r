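#' Odor panel
#'
#' The ordered set of odorant labels presented to the antenna, plus the label
#' of the mineral-oil control ("blank") stimulus.  The default panel is the
#' nine-odorant set used throughout: hexanol (HX), geraniol (GE), eugenol
#' (EU), citronellal (CO), citral (CA), ionone (IO), isoamyl acetate (IA),
#' benzaldehyde (BA), pyrrolidine (PY).
#'
#' @param odors character vector of unique odor labels.
#' @param blank_label label of the blank (control) stimulus; must not collide
#'   with an odor label.
#' @return An object of class `odor_panel`.
#' @examples
#' odor_panel()
#' @export
odor_panel <- function(odors = c("HX", "GE", "EU", "CO", "CA",
                                 "IO", "IA", "BA", "PY"),
                       blank_label = "blank") {
  odors <- as.character(odors)
  if (anyDuplicated(odors)) stop("odor labels must be unique")
  if (length(odors) < 2L) stop("need at least two odors")
  if (blank_label %in% odors) stop("blank_label must not be an odor label")
  structure(list(odors = odors, blank_label = blank_label),
            class = "odor_panel")
}

#' @export
print.odor_panel <- function(x, ...) {
  cat("<odor_panel> ", length(x$odors), " odors: ",
      paste(x$odors, collapse = ", "),
      " | blank: ", x$blank_label, "\n", sep = "")
  invisible(x)
}

#' Acquisition parameters
#'
#' Imaging and trial-structure parameters of a recording.  Defaults follow
#' wide-field single-wavelength imaging at ~18 Hz with 500 ms odor pulses.
#' The photobleaching model is a biexponential decay
#' \eqn{b(t) = a_1 e^{-t/\tau_1} + a_2 e^{-t/\tau_2}} acting
#' multiplicatively on the fluorescence; amplitudes are expressed as
#' fractions summing to 1 at \eqn{t = 0}.
#'
#' @param frame_rate frames per second (> 0).
#' @param trial_duration trial length in seconds.
#' @param stimulus_onset stimulus onset, seconds from trial start.
#' @param stimulus_duration stimulus pulse length, seconds.
#' @param bleach_a1,bleach_tau1 fast bleaching component: fractional
#'   amplitude and time constant (s).
#' @param bleach_a2,bleach_tau2 slow bleaching component.
#' @param noise_sigma acquisition noise SD in fluorescence arbitrary units
#'   (AU).  `NULL` means "use the regime default" (see [regime_defaults()]).
#' @param baseline_fluorescence_mean mean resting fluorescence, AU.
#' @return An object of class `acquisition_params`.
#' @examples
#' acquisition_params()
#' @export
acquisition_params <- function(frame_rate = 18,
                               trial_duration = 10,
                               stimulus_onset = 2,
                               stimulus_duration = 0.5,
                               bleach_a1 = 0.15, bleach_tau1 = 8,
                               bleach_a2 = 0.85, bleach_tau2 = 200,
                               noise_sigma = NULL,
                               baseline_fluorescence_mean = 1000) {
  stopifnot(frame_rate > 0, trial_duration > 0,
            stimulus_onset > 0,
            stimulus_onset + stimulus_duration < trial_duration,
            bleach_a1 >= 0, bleach_a2 >= 0,
            bleach_tau1 > 0, bleach_tau2 > 0,
            baseline_fluorescence_mean > 0)
  if (abs(bleach_a1 + bleach_a2 - 1) > 1e-8)
    stop("bleach amplitudes must sum to 1 at t = 0")
  if (!is.null(noise_sigma)) stopifnot(noise_sigma >= 0)
  structure(list(frame_rate = frame_rate,
                 trial_duration = trial_duration,
                 stimulus_onset = stimulus_onset,
                 stimulus_duration = stimulus_duration,
                 bleach_a1 = bleach_a1, bleach_tau1 = bleach_tau1,
                 bleach_a2 = bleach_a2, bleach_tau2 = bleach_tau2,
                 noise_sigma = noise_sigma,
                 baseline_fluorescence_mean = baseline_fluorescence_mean),
            class = "acquisition_params")
}

#' Frame-centre time axis of a trial
#'
#' Frames are sampled at frame centres, \eqn{t_i = (i + 0.5) / f} for
#' \eqn{i = 0, \dots, \lfloor T f \rfloor - 1}.
#'
#' @param acquisition an [acquisition_params()] object.
#' @return Numeric vector of frame times in seconds.
#' @export
time_axis <- function(acquisition) {
  n <- floor(acquisition$trial_duration * acquisition$frame_rate)
  (seq_len(n) - 0.5) / acquisition$frame_rate
}

#' Biexponential bleaching profile
#'
#' @param t time in seconds.
#' @param acquisition an [acquisition_params()] object.
#' @return `bleach_a1 * exp(-t/tau1) + bleach_a2 * exp(-t/tau2)`.
#' @keywords internal
bleach_profile <- function(t, acquisition) {
  acquisition$bleach_a1 * exp(-t / acquisition$bleach_tau1) +
    acquisition$bleach_a2 * exp(-t / acquisition$bleach_tau2)
}
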