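# Forward model for GCaMP6f-like population imaging: spike-triggered
# difference-of-exponentials calcium kernels on a per-cell baseline, with
# additive Gaussian noise, optional slow drift, and embedded coactive
# ensemble events with known ground truth.

#' Describe a population imaging scenario
#'
#' @param n_cells number of cells (ROIs).
#' @param duration recording length, seconds.
#' @param fps frame rate, frames per second (6-10 typical for the slow
#'   scan regimes this model emulates; default 10).
#' @param trains per-cell spike trains. Either a list of `n_cells`
#'   [make_spike_train()] objects, or a single list of arguments for
#'   [make_spike_train()] (without `duration`/`seed`) applied to every
#'   cell with per-cell sub-seeds.
#' @param ensemble_events list of coactive events, each a list with
#'   `time` (seconds) and `members` (cell indices): a spike is forced in
#'   every member at that time (plus optional uniform `jitter_frames`).
#' @param kernel list `(rise_tau, decay_tau, amplitude)`: double
#'   exponential calcium transient, seconds / seconds / peak dF/F0 per
#'   spike. Defaults 0.05 s, 0.5 s, 0.2 (fast-indicator values).
#' @param noise_sd additive Gaussian noise SD, dF/F0 units.
#' @param baseline_F0 per-cell baseline fluorescence, scalar or vector
#'   (arbitrary units, must be positive).
#' @param drift optional list `(amplitude, period)`: slow sinusoidal
#'   baseline trend in dF/F0 units over `period` seconds.
#' @param jitter_frames integer; members of an ensemble event are jittered
#'   uniformly within +/- this many frames (default 0 = same frame).
#' @param seed integer seed controlling every random draw in the scenario.
#' @return object of class `imaging_scenario`.
#' @export
imaging_scenario <- function(n_cells, duration, fps = 10, trains = list(pattern = "irregular", rate = 2),
                             ensemble_events = list(),
                             kernel = list(rise_tau = 0.05, decay_tau = 0.5, amplitude = 0.2),
                             noise_sd = 0, baseline_F0 = 100, drift = NULL,
                             jitter_frames = 0, seed = NULL) {
  check_positive(n_cells, "n_cells")
  check_positive(duration, "duration")
  check_positive(fps, "fps")
  check_nonneg(noise_sd, "noise_sd")
  kernel <- utils::modifyList(list(rise_tau = 0.05, decay_tau = 0.5, amplitude = 0.2), kernel)
  check_positive(kernel$rise_tau, "kernel$rise_tau")
  check_positive(kernel$decay_tau, "kernel$decay_tau")
  if (kernel$rise_tau >= kernel$decay_tau)
    stop_invalid("kernel rise_tau must be smaller than decay_tau")
  baseline_F0 <- rep(as.numeric(baseline_F0), length.out = n_cells)
  if (any(baseline_F0 <= 0)) stop_invalid("baseline_F0 must be positive")
  for (ev in ensemble_events) {
    if (is.null(ev$time) || is.null(ev$members))
      stop_invalid("each ensemble event needs 'time' and 'members'")
    if (any(ev$members < 1 | ev$members > n_cells))
      stop_invalid("ensemble member ids must be valid cell indices")
    if (ev$time < 0 || ev$time > duration)
      stop_invalid("ensemble event time outside recording")
  }
  structure(list(n_cells = as.integer(n_cells), duration = duration, fps = fps,
                 trains = trains, ensemble_events = ensemble_events,
                 kernel = kernel, noise_sd = noise_sd,
                 baseline_F0 = baseline_F0, drift = drift,
                 jitter_frames = as.integer(jitter_frames), seed = seed),
            class = "imaging_scenario")
}

# Resolve the per-cell spike trains of a scenario (deterministic in seed).
scenario_trains <- function(sc) {
  if (length(sc$trains) && inherits(sc$trains[[1]], "spike_train")) {
    if (length(sc$trains) != sc$n_cells)
      stop_invalid("need one spike_train per cell")
    return(sc$trains)
  }
  spec <- sc$trains
  lapply(seq_len(sc$n_cells), function(i) {
    do.call(make_spike_train,
            c(spec, list(duration = sc$duration, seed = derive_seed(sc$seed, i))))
  })
}

# Peak-normalised difference-of-exponentials kernel evaluated at lags u >= 0.
calcium_kernel <- function(u, rise_tau, decay_tau, amplitude) {
  tpk <- log(decay_tau / rise_tau) * rise_tau * decay_tau / (decay_tau - rise_tau)
  norm <- exp(-tpk / decay_tau) - exp(-tpk / rise_tau)
  amplitude * (exp(-u / decay_tau) - exp(-u / rise_tau)) / norm
}

#' Render fluorescence traces (and ground truth) from a scenario
#'
#' Each spike adds a peak-normalised double-exponential dF/F0 transient;
#' the fluorescence trace is `F0 * (1 + dff + drift + noise)`. Frames are
#' sampled instantaneously at frame-start times `(k - 1)/fps`. The
#' ground-truth raster marks the frame containing each spike.
#'
#' @param scenario an [imaging_scenario()].
#' @return list with `traces` ([fluor_traces()], background set to the
#'   baseline), `truth` (ground-truth [event_raster()]), `spike_times`
#'   (per-cell list including forced ensemble spikes) and `scenario`.
#' @export
render_fluorescence <- function(scenario) {
  sc <- scenario
  C <- round(sc$fps * sc$duration)
  if (C < 2) stop_invalid("duration * fps must give at least 2 frames")
  trains <- scenario_trains(sc)
  spike_times <- lapply(trains, `[[`, "spike_times")

  spike_times <- with_seed(derive_seed(sc$seed, 500000), {
    for (ev in sc$ensemble_events) {
      jit <- if (sc$jitter_frames > 0)
        sample(seq(-sc$jitter_frames, sc$jitter_frames), length(ev$members),
               replace = TRUE) / sc$fps
      else rep(0, length(ev$members))
      for (j in seq_along(ev$members)) {
        i <- ev$members[j]
        tev <- min(max(ev$time + jit[j], 0), sc$duration)
        spike_times[[i]] <- sort(c(spike_times[[i]], tev))
      }
    }
    spike_times
  })

  frame_t <- (seq_len(C) - 1) / sc$fps
  span <- ceiling(6 * sc$kernel$decay_tau * sc$fps)
  F <- matrix(0, sc$n_cells, C)
  A <- matrix(0L, sc$n_cells, C)
  for (i in seq_len(sc$n_cells)) {
    dff <- numeric(C)
    for (s in spike_times[[i]]) {
      k0 <- floor(s * sc$fps) + 1L
      if (k0 > C) k0 <- C
      A[i, k0] <- 1L
      # transient onset aligned to the start of the spike's frame: at
      # 6-10 fps the temporal precision of the recording is one frame,
      # and alignment makes the frame of the derivative jump (hence the
      # inferred event) coincide with the ground-truth frame.
      s_al <- frame_t[k0]
      idx <- k0:min(C, k0 + span)
      u <- frame_t[idx] - s_al
      dff[idx] <- dff[idx] +
        calcium_kernel(u, sc$kernel$rise_tau, sc$kernel$decay_tau,
                       sc$kernel$amplitude)
    }
    if (!is.null(sc$drift))
      dff <- dff + sc$drift$amplitude * sin(2 * pi * frame_t / sc$drift$period)
    F[i, ] <- dff
  }
  if (sc$noise_sd > 0) {
    F <- F + with_seed(derive_seed(sc$seed, 900000),
                       matrix(stats::rnorm(sc$n_cells * C, sd = sc$noise_sd),
                              sc$n_cells, C))
  }
  F <- sc$baseline_F0 * (1 + F)
  F[F < 0] <- 0

  list(traces = fluor_traces(F, sc$fps, background = sc$baseline_F0),
       truth = event_raster(A, sc$fps, condition_tag = "ground_truth"),
       spike_times = spike_times,
       scenario = sc)
}

#' Render a small synthetic movie with circular somata
#'
#' Draws each cell as a uniform disk whose intensity follows the cell's
#' fluorescence trace, on a constant background, and writes (optionally)
#' a 16-bit multi-page TIFF. Mean pixel intensity inside each disk
#' reproduces the trace up to 16-bit quantisation.
#'
#' @param scenario an [imaging_scenario()].
#' @param roi_radius disk radius, pixels.
#' @param field `c(width, height)` of the movie, pixels.
#' @param centers optional n_cells x 2 matrix of disk centres (x, y);
#'   defaults to a jittered grid. Disks must not overlap.
#' @param background_level background intensity, same units as traces.
#' @param path optional file path; when given the movie is written as a
#'   multi-page 16-bit TIFF and the ROI table as a sidecar CSV.
#' @return list with `frames` (list of matrices), `rois` (data.frame
#'   `id, x, y, radius, is_chat_positive`), `traces` and `truth` from
#'   [render_fluorescence()], and `scale` used for 16-bit encoding.
#' @export
render_movie <- function(scenario, roi_radius = 3, field = c(48, 48),
                         centers = NULL, background_level = 20, path = NULL) {
  rf <- render_fluorescence(scenario)
  n <- scenario$n_cells
  w <- field[1]; h <- field[2]
  if (is.null(centers)) {
    pitch <- 2 * roi_radius + 3
    per_row <- max(1L, floor((w - 2 * roi_radius - 2) / pitch) + 1L)
    gx <- roi_radius + 2 + ((seq_len(n) - 1) %% per_row) * pitch
    gy <- roi_radius + 2 + ((seq_len(n) - 1) %/% per_row) * pitch
    centers <- cbind(gx, gy)
  }
  if (n > 0) {
    if (any(centers[, 1] < roi_radius + 1 | centers[, 1] > w - roi_radius |
            centers[, 2] < roi_radius + 1 | centers[, 2] > h - roi_radius))
      stop_invalid("ROIs do not fit inside the field")
    if (n > 1) {
      dd <- as.matrix(stats::dist(centers))
      diag(dd) <- Inf
      if (any(dd < 2 * roi_radius + 1)) stop_invalid("ROIs overlap")
    }
  }
  C <- ncol(rf$traces$F)
  xs <- matrix(seq_len(w), h, w, byrow = TRUE)
  ys <- matrix(seq_len(h), h, w)
  masks <- lapply(seq_len(n), function(i) {
    (xs - centers[i, 1])^2 + (ys - centers[i, 2])^2 <= roi_radius^2
  })
  frames <- vector("list", C)
  for (k in seq_len(C)) {
    img <- matrix(background_level, h, w)
    for (i in seq_len(n)) img[masks[[i]]] <- rf$traces$F[i, k]
    frames[[k]] <- img
  }
  scale <- max(background_level, if (n > 0) max(rf$traces$F) else 0) * 1.05
  rois <- data.frame(id = if (n > 0) rf$traces$cell_ids else character(0),
                     x = if (n > 0) centers[, 1] else numeric(0),
                     y = if (n > 0) centers[, 2] else numeric(0),
                     radius = rep(roi_radius, n),
                     is_chat_positive = rep(TRUE, n))
  if (!is.null(path)) {
    tiff::writeTIFF(lapply(frames, function(f) f / scale), path,
                    bits.per.sample = 16L)
    utils::write.csv(rois, paste0(path, ".rois.csv"), row.names = FALSE)
  }
  list(frames = frames, rois = rois, traces = rf$traces, truth = rf$truth,
       scale = scale)
}
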