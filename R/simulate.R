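#' Sample the ground-truth response matrix of a simulated neuron
#'
#' Draws the noise-free peak calcium-drive amplitudes of every glomerulus for
#' every odor.  A shared tuning vector \eqn{d} (one entry per odor,
#' i.i.d. Uniform(0,1)) models drive that reaches all glomeruli (propagated
#' action potentials); per-glomerulus private vectors \eqn{p_g} (same
#' distribution) model local, glomerulus-specific input.  Row \eqn{g} of the
#' response matrix is
#' \deqn{A \, s_g \, \mathrm{norm}_1(\rho d + (1 - \rho) p_g),}
#' where \eqn{\rho} is `shared_weight_rho`, \eqn{s_g \sim}
#' LogNormal(0, 0.4) is a glomerular gain (neurite density varies between
#' glomeruli), \eqn{A} is `amplitude_scale`, and \eqn{\mathrm{norm}_1}
#' rescales a vector to maximum 1.  For `TYPE_IIA1`, private vectors are
#' shared within each of `n_groups` groups (glomeruli assigned round-robin),
#' emulating spikelet-coordinated groups of similarly tuned glomeruli.
#'
#' @param spec a [neuron_spec()].
#' @param panel an [odor_panel()].
#' @param rng_seed optional integer overriding `spec$seed`.
#' @return An object of class `ground_truth` with fields `response_matrix`
#'   (glomerulus x odor), `shared_tuning`, `private_tunings`, `gains`,
#'   `group_assignment`.
#' @examples
#' gt <- sample_ground_truth(neuron_spec("TYPE_I", 9, seed = 1), odor_panel())
#' stopifnot(all(gt$response_matrix >= 0))
#' @export
sample_ground_truth <- function(spec, panel = odor_panel(),
                                rng_seed = NULL) {
  stopifnot(inherits(spec, "neuron_spec"), inherits(panel, "odor_panel"))
  seed <- if (is.null(rng_seed)) spec$seed else as.integer(rng_seed)
  rho <- spec$shared_weight_rho
  if (rho < 0 || rho > 1) stop("shared_weight_rho must lie in [0, 1]")
  n_od <- length(panel$odors)
  n_gl <- spec$n_glomeruli

  d <- with_seed(substream_seed(seed, "tuning"), runif(n_od))
  gains <- with_seed(substream_seed(seed, "gains"), rlnorm(n_gl, 0, 0.4))

  if (spec$cell_type == "TYPE_IIA1") {
    group <- ((seq_len(n_gl) - 1L) %% spec$n_groups) + 1L
    group_vecs <- lapply(seq_len(spec$n_groups), function(k)
      with_seed(substream_seed(seed, "private", k), runif(n_od)))
    p <- do.call(rbind, group_vecs)[group, , drop = FALSE]
  } else {
    group <- rep(1L, n_gl)
    p <- do.call(rbind, lapply(seq_len(n_gl), function(g)
      with_seed(substream_seed(seed, "private", g), runif(n_od))))
  }

  resp <- matrix(0, n_gl, n_od,
                 dimnames = list(sprintf("g%02d", seq_len(n_gl)),
                                 panel$odors))
  for (g in seq_len(n_gl)) {
    v <- rho * d + (1 - rho) * p[g, ]
    resp[g, ] <- spec$amplitude_scale * gains[g] * v / max(v)
  }
  structure(list(response_matrix = resp,
                 shared_tuning = d,
                 private_tunings = p,
                 gains = gains,
                 group_assignment = group),
            class = "ground_truth")
}

#' Peak-normalised calcium response kernel
#'
#' Difference-of-exponentials transient,
#' \eqn{k(s) = (1 - e^{-s/\tau_r}) e^{-s/\tau_d}} for \eqn{s \ge 0},
#' rescaled so its continuous-time peak equals 1.
#'
#' @param t time in seconds relative to trial start.
#' @param onset stimulus onset (s).
#' @param tau_rise,tau_decay rise and decay time constants (s).
#' @return Kernel values; 0 before onset.
#' @keywords internal
response_kernel <- function(t, onset, tau_rise = 0.1, tau_decay = 1.5) {
  stopifnot(tau_rise < tau_decay)
  s <- pmax(t - onset, 0)
  raw <- (1 - exp(-s / tau_rise)) * exp(-s / tau_decay)
  s_pk <- tau_rise * log(1 + tau_decay / tau_rise)
  pk <- (1 - exp(-s_pk / tau_rise)) * exp(-s_pk / tau_decay)
  ifelse(t < onset, 0, raw / pk)
}

#' Synthesise one fluorescence trace
#'
#' Signal model:
#' \deqn{F(t) = B \, b(t) \, (1 + a \, k(t)) + \epsilon(t),}
#' with \eqn{B} the resting fluorescence, \eqn{b(t)} the multiplicative
#' biexponential bleaching profile, \eqn{a} the calcium-drive amplitude,
#' \eqn{k(t)} the peak-normalised response kernel, and \eqn{\epsilon}
#' i.i.d. Gaussian acquisition noise.
#'
#' @param amplitude drive amplitude \eqn{a \ge 0} (dimensionless; equals the
#'   peak dF/F0 the trace would show with perfect bleach correction).
#' @param acquisition an [acquisition_params()]; `noise_sigma` must be set
#'   (a bare `acquisition_params()` leaves it `NULL`, meaning regime
#'   default, which here falls back to the calibrated package default).
#' @param kernel_tau_rise,kernel_tau_decay kernel time constants (s).
#' @param rng_seed integer seed for the noise draw.
#' @param baseline optional resting fluorescence overriding
#'   `acquisition$baseline_fluorescence_mean`.
#' @return Numeric vector of fluorescence values (AU), one per frame.
#' @examples
#' acq <- acquisition_params(noise_sigma = 0)
#' f <- synthesize_trace(0, acq, rng_seed = 1)
#' stopifnot(all(abs(f - 1000 * bleach_profile(time_axis(acq), acq)) < 1e-9))
#' @export
synthesize_trace <- function(amplitude, acquisition,
                             kernel_tau_rise = 0.1, kernel_tau_decay = 1.5,
                             rng_seed = 0L, baseline = NULL) {
  if (amplitude < 0) stop("amplitude must be >= 0")
  sigma <- acquisition$noise_sigma
  if (is.null(sigma)) sigma <- .DEFAULT_NOISE_SIGMA
  B <- if (is.null(baseline)) acquisition$baseline_fluorescence_mean else baseline
  t <- time_axis(acquisition)
  k <- response_kernel(t, acquisition$stimulus_onset,
                       kernel_tau_rise, kernel_tau_decay)
  f <- B * bleach_profile(t, acquisition) * (1 + amplitude * k)
  if (sigma > 0)
    f <- f + with_seed(as.integer(rng_seed), rnorm(length(t), 0, sigma))
  # camera counts are non-negative: clip extreme noise excursions at 1 AU
  pmax(f, 1)
}

#' Generate a complete simulated recording for one neuron
#'
#' Draws the ground-truth response matrix, then synthesises one fluorescence
#' trace per (glomerulus, odor, trial) plus one blank (mineral-oil control)
#' trial per glomerulus with zero drive but full bleaching and noise.  The
#' neuron's resting fluorescence is drawn once from a lognormal around
#' `baseline_fluorescence_mean` (log-SD 0.3), emulating neuron-to-neuron
#' differences in indicator loading.
#'
#' @param spec a [neuron_spec()].
#' @param panel an [odor_panel()].
#' @param acquisition an [acquisition_params()].
#' @param n_trials trials per odor (default 1: single-sweep analysis).
#' @param neuron_id label for the neuron (default derived from the seed).
#' @return An object of class `simulated_recording` with fields `neuron_id`,
#'   `spec`, `acquisition`, `panel`, `traces` (nested list
#'   `[[glomerulus]][[stimulus]][[trial]]`), `time_axis`, `ground_truth`,
#'   `baseline`.
#' @examples
#' rec <- generate_recording(neuron_spec("TYPE_I", 9, seed = 1))
#' length(rec$traces)            # 9 glomeruli
#' names(rec$traces[[1]])        # 9 odors + blank
#' @export
generate_recording <- function(spec, panel = odor_panel(),
                               acquisition = acquisition_params(),
                               n_trials = 1L, neuron_id = NULL) {
  stopifnot(n_trials >= 1L)
  if (is.null(neuron_id)) neuron_id <- sprintf("sim_%s_%d", spec$cell_type,
                                               spec$seed)
  if (is.null(acquisition$noise_sigma))
    acquisition$noise_sigma <- spec$noise_sigma
  gt <- sample_ground_truth(spec, panel)
  B <- with_seed(substream_seed(spec$seed, "baseline"),
                 rlnorm(1, log(acquisition$baseline_fluorescence_mean),
                        .BASELINE_SDLOG))
  stims <- c(panel$odors, panel$blank_label)
  n_gl <- spec$n_glomeruli
  traces <- vector("list", n_gl)
  names(traces) <- rownames(gt$response_matrix)
  for (g in seq_len(n_gl)) {
    per_stim <- vector("list", length(stims))
    names(per_stim) <- stims
    for (s in seq_along(stims)) {
      stim <- stims[s]
      amp <- if (stim == panel$blank_label) 0 else gt$response_matrix[g, stim]
      nt <- if (stim == panel$blank_label) 1L else as.integer(n_trials)
      per_stim[[s]] <- lapply(seq_len(nt), function(tr)
        synthesize_trace(amp, acquisition,
                         rng_seed = substream_seed(spec$seed, "noise",
                                                   g * 10000L + s * 100L + tr),
                         baseline = B))
    }
    traces[[g]] <- per_stim
  }
  structure(list(neuron_id = neuron_id, spec = spec,
                 acquisition = acquisition, panel = panel,
                 traces = traces, time_axis = time_axis(acquisition),
                 ground_truth = gt, baseline = B),
            class = "simulated_recording")
}

#' @export
print.simulated_recording <- function(x, ...) {
  cat(sprintf("<simulated_recording> %s: %d glomeruli x %d stimuli, %d frames @ %.3g Hz\n",
              x$neuron_id, length(x$traces), length(x$traces[[1]]),
              length(x$time_axis), x$acquisition$frame_rate))
  invisible(x)
}
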