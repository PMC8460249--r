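#' Analysis parameters
#'
#' @param baseline_window_s length (s) of the pre-stimulus baseline used for
#'   F0 (window is `[onset - baseline_window_s, onset)`).
#' @param auc_window_s response quantification window after onset (s).
#' @param bleach_mode `"divide"` (default; bleaching is multiplicative) or
#'   `"subtract"`.
#' @param average_trials if `TRUE`, multi-trial AUCs are averaged per odor;
#'   default analyses single sweeps (trial 1).
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(baseline_window_s = 1, auc_window_s = 3,
                            bleach_mode = c("divide", "subtract"),
                            average_trials = FALSE) {
  bleach_mode <- match.arg(bleach_mode)
  stopifnot(baseline_window_s > 0, auc_window_s > 0)
  structure(list(baseline_window_s = baseline_window_s,
                 auc_window_s = auc_window_s,
                 bleach_mode = bleach_mode,
                 average_trials = average_trials),
            class = "analysis_config")
}

#' Run the full single-neuron analysis
#'
#' For every glomerulus: fit the biexponential bleaching model to that
#' glomerulus's blank trial ([fit_bleach()]), apply the correction to all of
#' its trials ([correct_bleach()]), convert to dF/F0 against the
#' pre-stimulus baseline ([compute_dff()]), quantify each odor response as
#' the area under the dF/F0 curve over the first `auc_window_s` seconds
#' after onset ([response_auc()]), and normalise the per-odor AUC vector to
#' the glomerulus maximum ([build_tuning_curve()]).  Responsive glomeruli
#' are then pairwise correlated ([correlation_matrix()]) and summarised
#' ([summarize_correlations()]).
#'
#' @param x a `simulated_recording` or `roi_trace_set`.  Each glomerulus
#'   must include a blank trial; without one, bleach correction is skipped
#'   for that glomerulus with a warning.
#' @param config an [analysis_config()].
#' @return An object of class `neuron_analysis`: `curves` (list of
#'   `tuning_curve`), `tuning` (long data frame), `matrix`
#'   (`correlation_matrix`), `heatmap` (clipped display matrix), `summary`
#'   (`correlation_summary`), `bleach_fits` (data frame).
#' @examples
#' rec <- generate_recording(neuron_spec("TYPE_I", 9, seed = 1,
#'                                       noise_sigma = 0))
#' res <- analyze_neuron(rec)
#' res$summary$mean_r   # 1: spiking regime forces rank-identical curves
#' @export
analyze_neuron <- function(x, config = analysis_config()) {
  if (inherits(x, "simulated_recording")) x <- as_roi_trace_set(x)
  stopifnot(inherits(x, "roi_trace_set"), inherits(config, "analysis_config"))
  acq <- x$acquisition
  if (is.null(acq)) stop("missing acquisition metadata (stimulus events)")
  onset <- acq$stimulus_onset
  tx <- x$time_axis
  blank <- x$panel$blank_label
  odors <- x$panel$odors
  bl_win <- c(onset - config$baseline_window_s, onset)

  curves <- list()
  fits <- list()
  for (g in names(x$traces)) {
    per_stim <- x$traces[[g]]
    if (!all(odors %in% names(per_stim)))
      stop("glomerulus ", g, " is missing odor trials")
    if (blank %in% names(per_stim)) {
      fit <- fit_bleach(per_stim[[blank]][[1L]], tx)
    } else {
      warning("glomerulus ", g,
              " has no blank trial; bleach correction skipped")
      fit <- fit_bleach(rep(1, length(tx)) * mean(per_stim[[odors[1]]][[1L]]),
                        tx)  # flat fit: identity correction
    }
    fits[[g]] <- data.frame(glomerulus = g, a1 = fit$a1, tau1 = fit$tau1,
                            a2 = fit$a2, tau2 = fit$tau2, c = fit$c,
                            rss = fit$rss, converged = fit$converged)
    auc_of <- function(trace) {
      corr <- correct_bleach(trace, fit, tx, mode = config$bleach_mode)
      d <- compute_dff(corr, tx, bl_win)
      response_auc(d$dff, tx, onset, config$auc_window_s)
    }
    aucs <- vapply(odors, function(o) {
      trials <- per_stim[[o]]
      if (config$average_trials) mean(vapply(trials, auc_of, 0))
      else auc_of(trials[[1L]])
    }, 0)
    blank_auc <- if (blank %in% names(per_stim))
      auc_of(per_stim[[blank]][[1L]]) else NA_real_
    curves[[g]] <- build_tuning_curve(aucs, blank_auc, glomerulus = g)
  }

  mat <- correlation_matrix(curves)
  summ <- summarize_correlations(mat, neuron_id = x$neuron_id,
                                 cell_type = x$cell_type)
  structure(list(curves = curves,
                 tuning = tuning_table(curves, x$neuron_id),
                 matrix = mat,
                 heatmap = heatmap_matrix(mat),
                 summary = summ,
                 bleach_fits = do.call(rbind, fits)),
            class = "neuron_analysis")
}

#' @export
print.neuron_analysis <- function(x, ...) {
  print(x$summary)
  if (length(x$matrix$excluded))
    cat("  excluded non-responsive glomeruli: ",
        paste(x$matrix$excluded, collapse = ", "), "\n")
  invisible(x)
}

# Distinct deterministic master seed for neuron `index` of a regime roster.
# The regime label is hashed in so that, e.g., control and spike-suppressed
# rosters built from the same index range use independent random streams.
roster_seed <- function(cell_type, index) {
  substream_seed(as.integer(index), paste0("roster:", cell_type))
}

#' Simulate a roster of neurons of one regime
#'
#' Neuron `i` uses master seed derived from `seed_start + i - 1` combined
#' with the regime label.  Unless fixed, the number of innervated glomeruli
#' is drawn uniformly from 9 to 25 per neuron, the per-neuron range observed
#' in this class of recordings.
#'
#' @param cell_type regime label ([cell_types]).
#' @param n_neurons number of neurons.
#' @param seed_start first roster index (default 1).
#' @param panel,acquisition shared stimulus panel and acquisition settings.
#' @param shared_weight_rho,noise_sigma,amplitude_scale optional overrides
#'   of the regime defaults.
#' @param n_glomeruli optional fixed glomerulus count.
#' @param n_trials trials per odor.
#' @return List of `simulated_recording` objects.
#' @export
simulate_roster <- function(cell_type, n_neurons, seed_start = 1L,
                            panel = odor_panel(),
                            acquisition = acquisition_params(),
                            shared_weight_rho = NULL, noise_sigma = NULL,
                            amplitude_scale = NULL, n_glomeruli = NULL,
                            n_trials = 1L) {
  lapply(seq_len(n_neurons), function(i) {
    idx <- seed_start + i - 1L
    master <- roster_seed(cell_type, idx)
    n_gl <- if (is.null(n_glomeruli)) {
      with_seed(substream_seed(master, "n_glomeruli"), sample(9:25, 1L))
    } else n_glomeruli
    spec <- neuron_spec(cell_type, n_gl, seed = master,
                        shared_weight_rho = shared_weight_rho,
                        noise_sigma = noise_sigma,
                        amplitude_scale = amplitude_scale)
    generate_recording(spec, panel, acquisition, n_trials = n_trials,
                       neuron_id = sprintf("%s_%03d", cell_type, idx))
  })
}

# Grand mean of per-neuron mean Spearman r for a simulated roster.
roster_mean_r <- function(cell_type, n_neurons, seed_start = 1L,
                          config = analysis_config(), ...) {
  recs <- simulate_roster(cell_type, n_neurons, seed_start, ...)
  vapply(recs, function(r) analyze_neuron(r, config)$summary$mean_r, 0)
}

#' Calibrate the shared-weight parameter against a target mean correlation
#'
#' The generator's regimes are tied to observed group statistics through a
#' single knob: the fraction rho of tuning variance shared across glomeruli.
#' This routine bisects rho in `[0, 1]` until the Monte-Carlo grand mean of
#' per-neuron mean Spearman r (full pipeline, `n_monte_carlo` neurons with
#' fixed seeds) is within `tol` of `target_mean_r`.  The grand mean is
#' monotonically nondecreasing in rho under fixed seeds, which bisection
#' relies on.
#'
#' @param target_mean_r target grand mean Spearman r in `[0, 1]`.
#' @param cell_type regime template whose other defaults (amplitude scale,
#'   grouping, noise) are held fixed.
#' @param n_monte_carlo neurons per evaluation.
#' @param tol convergence tolerance on the achieved grand mean.
#' @param seed_start roster seed for the Monte-Carlo neurons.
#' @param max_iter bisection iteration cap.
#' @param ... passed to [simulate_roster()] (e.g. `noise_sigma`).
#' @return List with `rho`, `achieved`, `iterations`.
#' @export
calibrate_shared_weight <- function(target_mean_r, cell_type,
                                    n_monte_carlo = 40L, tol = 0.02,
                                    seed_start = 900001L, max_iter = 20L,
                                    ...) {
  stopifnot(target_mean_r >= 0, target_mean_r <= 1)
  eval_rho <- function(rho)
    mean(roster_mean_r(cell_type, n_monte_carlo, seed_start,
                       shared_weight_rho = rho, ...))
  lo <- 0; hi <- 1
  f_lo <- eval_rho(lo); f_hi <- eval_rho(hi)
  if (target_mean_r > f_hi + tol || target_mean_r < f_lo - tol)
    stop(sprintf("target %.3f unreachable; achievable grand mean range is [%.3f, %.3f]",
                 target_mean_r, f_lo, f_hi))
  if (abs(f_lo - target_mean_r) <= tol && f_lo >= f_hi - tol)
    return(list(rho = lo, achieved = f_lo, iterations = 0L))
  it <- 0L; mid <- (lo + hi) / 2; f_mid <- NA_real_
  repeat {
    it <- it + 1L
    mid <- (lo + hi) / 2
    f_mid <- eval_rho(mid)
    if (abs(f_mid - target_mean_r) <= tol || it >= max_iter) break
    if (f_mid < target_mean_r) lo <- mid else hi <- mid
  }
  list(rho = mid, achieved = f_mid, iterations = it)
}

#' Calibrate the acquisition noise level for the spiking regime
#'
#' In the spiking (TYPE_I) regime all glomeruli share one tuning profile, so
#' the only departure of pairwise Spearman r from 1 comes from acquisition
#' noise.  This routine bisects the noise SD until the grand mean per-neuron
#' mean r over `n_monte_carlo` simulated TYPE_I neurons matches the target.
#'
#' @param target_mean_r target grand mean (e.g. 0.95).
#' @param n_monte_carlo neurons per evaluation.
#' @param tol tolerance on the achieved grand mean.
#' @param sigma_range search interval for the noise SD (AU).
#' @param seed_start roster seed.
#' @param max_iter bisection cap.
#' @return List with `noise_sigma`, `achieved`, `iterations`.
#' @export
calibrate_noise_sigma <- function(target_mean_r = 0.95, n_monte_carlo = 40L,
                                  tol = 0.005, sigma_range = c(0, 200),
                                  seed_start = 900001L, max_iter = 20L) {
  eval_sigma <- function(s)
    mean(roster_mean_r("TYPE_I", n_monte_carlo, seed_start,
                       noise_sigma = s))
  lo <- sigma_range[1]; hi <- sigma_range[2]
  f_lo <- eval_sigma(lo); f_hi <- eval_sigma(hi)
  if (target_mean_r > f_lo + tol || target_mean_r < f_hi - tol)
    stop(sprintf("target %.3f unreachable; achievable range is [%.3f, %.3f]",
                 target_mean_r, f_hi, f_lo))
  it <- 0L; mid <- mean(sigma_range); f_mid <- NA_real_
  repeat {
    it <- it + 1L
    mid <- (lo + hi) / 2
    f_mid <- eval_sigma(mid)
    if (abs(f_mid - target_mean_r) <= tol || it >= max_iter) break
    if (f_mid > target_mean_r) lo <- mid else hi <- mid
  }
  list(noise_sigma = mid, achieved = f_mid, iterations = it)
}

#' Run a complete simulated experiment
#'
#' Simulates a roster of neurons per regime, runs [analyze_neuron()] on each,
#' aggregates per-neuron correlation summaries, and — when at least two
#' groups have two or more neurons — compares groups with Kruskal-Wallis and
#' Dunn post hoc tests plus Tukey box statistics.  Neurons whose analysis
#' fails (e.g. fewer than two responsive glomeruli) are collected under
#' `failures` and excluded from the group tables; the run continues.
#'
#' @param roster named integer vector or list, neurons per regime, e.g.
#'   `c(TYPE_I = 16, TYPE_I_HYPERPOL = 6, TYPE_I_QX314 = 5)`.
#' @param seed master experiment seed; roster indices start at
#'   `(seed - 1) * 1000 + 1`, so different seeds yield disjoint neuron
#'   seed ranges.
#' @param panel,acquisition,config shared settings.
#' @param n_trials trials per odor.
#' @return An object of class `experiment_report`: `summaries` (data
#'   frame), `groups` (list of per-group mean_r vectors), `stats`
#'   ([compare_groups()] output or `NULL`), `failures`, `provenance`.
#' @examples
#' \donttest{
#' rep <- run_experiment(c(TYPE_I = 3), seed = 1)
#' rep$summaries$mean_r
#' }
#' @export
run_experiment <- function(roster, seed = 1L, panel = odor_panel(),
                           acquisition = acquisition_params(),
                           config = analysis_config(), n_trials = 1L) {
  roster <- unlist(roster)
  if (length(roster) == 0L || is.null(names(roster)) ||
      any(!nzchar(names(roster))))
    stop("roster must be a named vector of neuron counts")
  seed_start <- (as.integer(seed) - 1L) * 1000L + 1L
  analyses <- list(); failures <- list()
  for (ct in names(roster)) {
    recs <- simulate_roster(ct, roster[[ct]], seed_start,
                            panel = panel, acquisition = acquisition,
                            n_trials = n_trials)
    for (rec in recs) {
      res <- tryCatch(analyze_neuron(rec, config), error = function(e) e)
      if (inherits(res, "error")) {
        failures[[rec$neuron_id]] <- conditionMessage(res)
      } else {
        analyses[[rec$neuron_id]] <- res
      }
    }
  }
  if (length(analyses) == 0L) stop("no neuron could be analysed")
  summaries <- summary_table(lapply(analyses, function(a) a$summary))
  groups <- split(summaries$mean_r, summaries$cell_type)
  groups <- groups[intersect(names(roster), names(groups))]  # roster order
  stats <- if (length(groups) >= 2L && all(lengths(groups) >= 2L))
    compare_groups(groups) else NULL
  structure(list(summaries = summaries, groups = groups, stats = stats,
                 analyses = analyses, failures = failures,
                 provenance = list(
                   roster = as.list(roster), seed = as.integer(seed),
                   seed_start = seed_start,
                   config = unclass(config),
                   package_version =
                     as.character(utils::packageVersion("glomtune")))),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report> ", nrow(x$summaries), " neurons in ",
      length(x$groups), " group(s)\n", sep = "")
  for (g in names(x$groups))
    cat(sprintf("  %-16s N=%2d  mean r = %.3f +/- %.3f\n", g,
                length(x$groups[[g]]), mean(x$groups[[g]]),
                sd(x$groups[[g]])))
  if (!is.null(x$stats))
    cat(sprintf("  Kruskal-Wallis H = %.3f, df = %d, p = %.4g\n",
                x$stats$omnibus$H, x$stats$omnibus$df, x$stats$omnibus$p))
  if (length(x$failures))
    cat("  failed neurons:", paste(names(x$failures), collapse = ", "), "\n")
  invisible(x)
}
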