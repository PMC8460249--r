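# File formats
#
# Trace CSV (long, one row per frame):
#   neuron_id, cell_type, glomerulus, stimulus, trial, frame, time_s,
#   fluorescence_au
# Events CSV (one row per stimulus x trial):
#   neuron_id, stimulus, trial, onset_s, duration_s, is_blank
# Ground-truth JSON per neuron: response matrix, tuning vectors, seeds.
# Image stacks: multi-page 16-bit TIFF (frames, AU stored as rounded
# integers) plus a single-page 16-bit integer TIFF label mask.

#' Flatten recordings to the long trace format
#'
#' @param x a `simulated_recording`/`roi_trace_set` or a list of them.
#' @return data.frame in the long trace-CSV layout.
#' @export
as_trace_df <- function(x) {
  if (inherits(x, "simulated_recording")) x <- as_roi_trace_set(x)
  if (inherits(x, "roi_trace_set")) x <- list(x)
  dt_list <- lapply(x, function(ts) {
    if (inherits(ts, "simulated_recording")) ts <- as_roi_trace_set(ts)
    rows <- list()
    for (g in names(ts$traces)) for (s in names(ts$traces[[g]])) {
      trials <- ts$traces[[g]][[s]]
      for (tr in seq_along(trials)) {
        rows[[length(rows) + 1L]] <- data.table::data.table(
          neuron_id = ts$neuron_id,
          cell_type = if (is.na(ts$cell_type)) "" else ts$cell_type,
          glomerulus = g, stimulus = s, trial = tr,
          frame = seq_along(trials[[tr]]),
          time_s = ts$time_axis,
          fluorescence_au = trials[[tr]])
      }
    }
    data.table::rbindlist(rows)
  })
  as.data.frame(data.table::rbindlist(dt_list))
}

#' Write / read the long trace CSV
#'
#' @param x recordings (see [as_trace_df()]).
#' @param path CSV path.
#' @return `write_traces_csv`: the path, invisibly.
#' @export
write_traces_csv <- function(x, path) {
  data.table::fwrite(as_trace_df(x), path)
  invisible(path)
}

#' @rdname write_traces_csv
#' @param events_path path of the companion events CSV (needed to identify
#'   the blank stimulus and the onset).
#' @return `read_traces_csv`: a named list of `roi_trace_set`, one per
#'   neuron.
#' @export
read_traces_csv <- function(path, events_path) {
  df <- data.table::fread(path, data.table = FALSE)
  ev <- data.table::fread(events_path, data.table = FALSE)
  need <- c("neuron_id", "glomerulus", "stimulus", "trial", "frame",
            "time_s", "fluorescence_au")
  if (!all(need %in% names(df)))
    stop("trace CSV is missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  out <- list()
  for (nid in unique(df$neuron_id)) {
    sub <- df[df$neuron_id == nid, ]
    ev_sub <- ev[ev$neuron_id == nid, ]
    if (nrow(ev_sub) == 0L) stop("no stimulus events for neuron ", nid)
    blank <- unique(ev_sub$stimulus[as.logical(ev_sub$is_blank)])
    odors <- unique(ev_sub$stimulus[!as.logical(ev_sub$is_blank)])
    if (length(blank) != 1L) stop("expected exactly one blank stimulus")
    tx <- sort(unique(sub$time_s))
    dt <- stats::median(diff(tx))
    onset <- unique(ev_sub$onset_s)[1]
    dur <- unique(ev_sub$duration_s)[1]
    acq <- acquisition_params(frame_rate = 1 / dt,
                              trial_duration = length(tx) * dt,
                              stimulus_onset = onset,
                              stimulus_duration = dur)
    traces <- list()
    ord <- order(sub$glomerulus, sub$stimulus, sub$trial, sub$frame)
    sub <- sub[ord, ]
    for (g in unique(sub$glomerulus)) {
      gsub <- sub[sub$glomerulus == g, ]
      per_stim <- list()
      for (s in c(odors, blank)) {
        ssub <- gsub[gsub$stimulus == s, ]
        per_stim[[s]] <- lapply(sort(unique(ssub$trial)), function(tr)
          ssub$fluorescence_au[ssub$trial == tr])
      }
      traces[[g]] <- per_stim
    }
    ct <- if ("cell_type" %in% names(sub))
      as.character(sub$cell_type[1]) else NA_character_
    if (isTRUE(ct == "")) ct <- NA_character_
    out[[nid]] <- roi_trace_set(traces, tx, acquisition = acq,
                                panel = odor_panel(odors, blank),
                                neuron_id = nid, cell_type = ct)
  }
  out
}

#' Write / read the stimulus-events CSV
#'
#' @param x recordings (list or single).
#' @param path CSV path.
#' @export
write_events_csv <- function(x, path) {
  if (!is.list(x) || inherits(x, c("simulated_recording", "roi_trace_set")))
    x <- list(x)
  rows <- lapply(x, function(r) {
    if (inherits(r, "simulated_recording")) r <- as_roi_trace_set(r)
    stims <- names(r$traces[[1]])
    n_tr <- vapply(r$traces[[1]], length, 1L)
    data.frame(neuron_id = r$neuron_id,
               stimulus = rep(stims, n_tr),
               trial = unlist(lapply(n_tr, seq_len)),
               onset_s = r$acquisition$stimulus_onset,
               duration_s = r$acquisition$stimulus_duration,
               is_blank = rep(stims == r$panel$blank_label, n_tr),
               row.names = NULL)
  })
  data.table::fwrite(data.table::rbindlist(rows), path)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  data.table::fread(path, data.table = FALSE)
}

#' Write / read per-neuron ground truth as JSON
#'
#' Stores the noise-free response matrix, tuning vectors, gains, grouping
#' and seeds of a simulated recording, for parameter-recovery tests.
#'
#' @param recording a `simulated_recording`.
#' @param path JSON path.
#' @export
write_ground_truth_json <- function(recording, path) {
  gt <- recording$ground_truth
  jsonlite::write_json(list(
    neuron_id = recording$neuron_id,
    cell_type = recording$spec$cell_type,
    seed = recording$spec$seed,
    shared_weight_rho = recording$spec$shared_weight_rho,
    amplitude_scale = recording$spec$amplitude_scale,
    noise_sigma = recording$spec$noise_sigma,
    baseline = recording$baseline,
    odors = recording$panel$odors,
    glomeruli = rownames(gt$response_matrix),
    response_matrix = gt$response_matrix,
    shared_tuning = gt$shared_tuning,
    gains = gt$gains,
    group_assignment = gt$group_assignment
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth_json
#' @export
read_ground_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$response_matrix <- matrix(unlist(x$response_matrix),
                              nrow = length(x$glomeruli), byrow = FALSE,
                              dimnames = list(x$glomeruli, x$odors))
  x
}

# 16-bit quantisation scale for stack TIFFs (camera AU are 16-bit integers)
.TIFF_MAX <- 65535

#' Write / read a labelled image stack as TIFF
#'
#' Frames go to a multi-page 16-bit TIFF (values rounded to integer AU;
#' fluorescence must lie in [0, 65535]); the label mask goes to a
#' single-page 16-bit TIFF holding the integer labels.
#'
#' @param stack a `labeled_stack`.
#' @param frames_path,mask_path output TIFF paths.
#' @export
write_labeled_stack <- function(stack, frames_path, mask_path) {
  stopifnot(inherits(stack, "labeled_stack"))
  fr <- stack$frames
  if (min(fr) < 0 || max(fr) > .TIFF_MAX)
    stop("fluorescence outside the 16-bit range [0, 65535]")
  pages <- lapply(seq_len(dim(fr)[1]), function(i)
    round(fr[i, , ]) / .TIFF_MAX)
  tiff::writeTIFF(pages, frames_path, bits.per.sample = 16L,
                  compression = "none")
  tiff::writeTIFF(stack$label_mask / .TIFF_MAX, mask_path,
                  bits.per.sample = 16L, compression = "none")
  invisible(frames_path)
}

#' @rdname write_labeled_stack
#' @param acquisition an [acquisition_params()] describing the trial grid
#'   (used to rebuild the time axis and epochs).
#' @param panel an [odor_panel()]; when given and the page count is a
#'   multiple of the frames per trial, epochs are reconstructed in panel
#'   order (odors then blank).
#' @param neuron_id label.
#' @return `read_labeled_stack`: a `labeled_stack`.
#' @export
read_labeled_stack <- function(frames_path, mask_path,
                               acquisition = acquisition_params(),
                               panel = odor_panel(), neuron_id = "neuron") {
  pages <- tiff::readTIFF(frames_path, all = TRUE)
  mask <- round(tiff::readTIFF(mask_path) * .TIFF_MAX)
  storage.mode(mask) <- "integer"
  fr <- array(0, dim = c(length(pages), nrow(mask), ncol(mask)))
  for (i in seq_along(pages)) fr[i, , ] <- round(pages[[i]] * .TIFF_MAX)
  n_trial <- floor(acquisition$trial_duration * acquisition$frame_rate)
  epochs <- NULL
  if (!is.null(panel)) {
    stims <- c(panel$odors, panel$blank_label)
    if (length(pages) == n_trial * length(stims))
      epochs <- data.frame(stimulus = stims,
                           start_frame = (seq_along(stims) - 1L) * n_trial + 1L,
                           end_frame = seq_along(stims) * n_trial,
                           stringsAsFactors = FALSE)
  }
  dt <- 1 / acquisition$frame_rate
  structure(list(frames = fr, label_mask = mask,
                 time_axis = (seq_len(length(pages)) - 0.5) * dt,
                 epochs = epochs, acquisition = acquisition,
                 panel = panel, neuron_id = neuron_id),
            class = "labeled_stack")
}

#' Write an experiment report to a directory
#'
#' Emits `summaries.csv` (per-neuron correlation summaries), per-neuron
#' tuning and correlation-matrix CSVs (raw and display-clipped), bleach-fit
#' tables, `groups.csv`, and `stats.json` (omnibus and pairwise tests, box
#' statistics, provenance).
#'
#' @param report an [run_experiment()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "experiment_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(report$summaries, file.path(dir, "summaries.csv"))
  grp <- do.call(rbind, lapply(names(report$groups), function(g)
    data.frame(group = g,
               neuron_id = report$summaries$neuron_id[
                 report$summaries$cell_type == g],
               mean_r = report$groups[[g]], row.names = NULL)))
  data.table::fwrite(grp, file.path(dir, "groups.csv"))
  for (nid in names(report$analyses)) {
    a <- report$analyses[[nid]]
    ndir <- file.path(dir, "neurons", nid)
    dir.create(ndir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(a$tuning, file.path(ndir, "tuning.csv"))
    data.table::fwrite(as.data.frame(a$matrix$r),
                       file.path(ndir, "correlation_matrix.csv"),
                       row.names = TRUE)
    data.table::fwrite(as.data.frame(a$heatmap$r),
                       file.path(ndir, "correlation_heatmap.csv"),
                       row.names = TRUE)
    data.table::fwrite(a$bleach_fits, file.path(ndir, "bleach_fits.csv"))
  }
  stats <- report$stats
  jsonlite::write_json(list(
    omnibus = stats$omnibus,
    pairwise = stats$pairwise,
    box = stats$box,
    group_n = as.list(stats$n),
    failures = report$failures,
    provenance = report$provenance
  ), file.path(dir, "stats.json"), auto_unbox = TRUE, digits = NA,
     null = "null")
  invisible(dir)
}
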