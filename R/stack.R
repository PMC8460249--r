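#' Render a simulated recording as a label-masked image stack
#'
#' Places one non-overlapping disk per glomerulus on an H x W field and
#' renders every stimulus epoch of the recording in panel order (odors, then
#' the blank) as consecutive frames.  At frame t, pixels of glomerulus g are
#' i.i.d. Gaussian around that glomerulus's trace value; background pixels
#' are Gaussian around `background`.  The integer label mask records disk
#' placement (0 = background, k = k-th glomerulus).
#'
#' @param recording a [generate_recording()] result.
#' @param height,width image size in pixels.
#' @param rng_seed integer seed for disk placement and pixel noise.
#' @param radius disk radius in pixels (>= 3, so every ROI has >= 20
#'   pixels).
#' @param pixel_sigma per-pixel Gaussian noise SD (AU).
#' @param background mean background intensity (AU).
#' @param trial trial index rendered for each odor.
#' @return An object of class `labeled_stack`: `frames` (T x H x W array),
#'   `label_mask` (H x W integer matrix), `time_axis`, `epochs` (data frame
#'   stimulus / start_frame / end_frame), `acquisition`, `neuron_id`.
#' @export
render_stack <- function(recording, height = 64L, width = 64L,
                         rng_seed = 1L, radius = 4L,
                         pixel_sigma = 10, background = 100,
                         trial = 1L) {
  stopifnot(inherits(recording, "simulated_recording"), radius >= 3L)
  n_gl <- length(recording$traces)
  centers <- place_disks(n_gl, height, width, radius,
                         seed = substream_seed(rng_seed, "placement"))
  mask <- matrix(0L, height, width)
  for (g in seq_len(n_gl)) {
    cx <- centers[g, 1]; cy <- centers[g, 2]
    for (i in max(1, cx - radius):min(height, cx + radius))
      for (j in max(1, cy - radius):min(width, cy + radius))
        if ((i - cx)^2 + (j - cy)^2 <= radius^2) mask[i, j] <- g
  }
  if (any(tabulate(mask[mask > 0], n_gl) < 20L))
    stop("internal error: a glomerulus has fewer than 20 pixels")

  stims <- c(recording$panel$odors, recording$panel$blank_label)
  n_frames_trial <- length(recording$time_axis)
  total <- n_frames_trial * length(stims)
  frames <- array(0, dim = c(total, height, width))
  epochs <- data.frame(stimulus = stims,
                       start_frame = (seq_along(stims) - 1L) * n_frames_trial + 1L,
                       end_frame = seq_along(stims) * n_frames_trial,
                       stringsAsFactors = FALSE)
  idx_by_label <- lapply(seq_len(n_gl), function(g) which(mask == g))
  bg_idx <- which(mask == 0L)
  set.seed(substream_seed(rng_seed, "pixels"))
  for (s in seq_along(stims)) {
    stim <- stims[s]
    for (ti in seq_len(n_frames_trial)) {
      fr <- matrix(0, height, width)
      fr[bg_idx] <- background
      for (g in seq_len(n_gl)) {
        tr_idx <- if (stim == recording$panel$blank_label) 1L else trial
        fr[idx_by_label[[g]]] <- recording$traces[[g]][[stim]][[tr_idx]][ti]
      }
      if (pixel_sigma > 0)
        fr <- fr + matrix(rnorm(height * width, 0, pixel_sigma), height, width)
      frames[(s - 1L) * n_frames_trial + ti, , ] <- fr
    }
  }
  dt <- 1 / recording$acquisition$frame_rate
  structure(list(frames = frames, label_mask = mask,
                 time_axis = (seq_len(total) - 0.5) * dt,
                 epochs = epochs,
                 acquisition = recording$acquisition,
                 panel = recording$panel,
                 neuron_id = recording$neuron_id),
            class = "labeled_stack")
}

# Rejection-sample non-overlapping disk centres; bounded retries.
place_disks <- function(n, height, width, radius, seed,
                        max_tries = 500L) {
  margin <- radius + 1L
  if (height < 2 * margin || width < 2 * margin)
    stop("field too small for the requested disk radius")
  set.seed(seed)
  centers <- matrix(NA_real_, n, 2)
  for (g in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      cx <- sample(margin:(height - margin), 1L)
      cy <- sample(margin:(width - margin), 1L)
      if (g == 1L ||
          all((centers[seq_len(g - 1L), 1] - cx)^2 +
              (centers[seq_len(g - 1L), 2] - cy)^2 >
              (2 * radius + 1)^2)) {
        centers[g, ] <- c(cx, cy); ok <- TRUE; break
      }
    }
    if (!ok) stop("could not place ", n, " non-overlapping disks in ",
                  height, "x", width, "; enlarge the field or shrink radius")
  }
  centers
}

#' Extract per-glomerulus mean traces from a label-masked stack
#'
#' The trace of glomerulus g at frame t is the unweighted arithmetic mean of
#' frame t over all pixels with label g.  Labels are processed in ascending
#' order.  When the stack carries stimulus epochs (as stacks from
#' [render_stack()] do), the concatenated trace is split back into
#' per-stimulus trials and returned as a `roi_trace_set`; otherwise a plain
#' matrix of traces is returned.
#'
#' @param stack a `labeled_stack`, or a T x H x W array.
#' @param label_mask H x W integer matrix (required when `stack` is a bare
#'   array).
#' @param required_labels optional integer vector of labels that must be
#'   present in the mask; missing ones raise an error.
#' @return A `roi_trace_set` (see [roi_trace_set()]) when epochs are
#'   available, else a T x n_labels matrix with one column per label.
#' @export
extract_roi_traces <- function(stack, label_mask = NULL,
                               required_labels = NULL) {
  if (inherits(stack, "labeled_stack")) {
    frames <- stack$frames
    if (is.null(label_mask)) label_mask <- stack$label_mask
  } else frames <- stack
  if (is.null(label_mask)) stop("label_mask is required")
  dm <- dim(frames)
  if (length(dm) != 3L || dm[2] != nrow(label_mask) || dm[3] != ncol(label_mask))
    stop("frame dimensions do not match the label mask")
  labels <- sort(unique(as.integer(label_mask[label_mask > 0])))
  if (length(labels) == 0L) stop("label mask contains no positive labels")
  if (!is.null(required_labels) && !all(required_labels %in% labels))
    stop("labels absent from mask: ",
         paste(setdiff(required_labels, labels), collapse = ", "))
  flat <- matrix(frames, nrow = dm[1])  # frames x (H*W), column-major pixels
  tr <- vapply(labels, function(g) {
    idx <- which(as.vector(label_mask) == g)
    if (length(idx) == 1L) flat[, idx] else rowMeans(flat[, idx, drop = FALSE])
  }, numeric(dm[1]))
  colnames(tr) <- sprintf("g%02d", labels)

  if (!inherits(stack, "labeled_stack") || is.null(stack$epochs))
    return(tr)

  # split concatenated epochs back into per-stimulus trials
  traces <- vector("list", length(labels))
  names(traces) <- colnames(tr)
  for (gi in seq_along(labels)) {
    per_stim <- list()
    for (e in seq_len(nrow(stack$epochs))) {
      stim <- stack$epochs$stimulus[e]
      seg <- tr[stack$epochs$start_frame[e]:stack$epochs$end_frame[e], gi]
      per_stim[[stim]] <- list(seg)
    }
    traces[[gi]] <- per_stim
  }
  roi_trace_set(traces, time_axis = time_axis(stack$acquisition),
                acquisition = stack$acquisition, panel = stack$panel,
                neuron_id = stack$neuron_id)
}
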