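# From fluorescence to binary event rasters: dF/F0, its time derivative,
# and derivative thresholding at a multiple of the baseline SD.

#' Extract ROI traces from a movie
#'
#' Per-cell trace = mean pixel value inside each circular ROI; per-cell
#' background = mean value in a surrounding annulus, excluding pixels
#' belonging to any ROI disk. Edge ROIs whose annulus is empty fall back
#' to the global frame mean with a warning.
#'
#' @param frames list of numeric matrices (one per frame), or a file path
#'   to a multi-page TIFF.
#' @param rois data.frame with columns `id, x, y, radius` (pixels), as
#'   written by [render_movie()].
#' @param annulus_width annulus thickness, pixels.
#' @param fps frame rate of the movie, frames per second.
#' @return a [fluor_traces()] with `background` set to the annulus means
#'   (cells x frames matrix).
#' @export
extract_roi_traces <- function(frames, rois, annulus_width = 2, fps = 10) {
  if (is.character(frames)) {
    frames <- tiff::readTIFF(frames, all = TRUE)
    if (is.matrix(frames)) frames <- list(frames)
  }
  if (!length(frames)) stop_invalid("movie has no frames")
  h <- nrow(frames[[1]]); w <- ncol(frames[[1]])
  n <- nrow(rois)
  if (n == 0) {
    return(fluor_traces(matrix(0, 0, length(frames)), fps,
                        cell_ids = character(0)))
  }
  if (any(rois$x - rois$radius < 1 | rois$x + rois$radius > w |
          rois$y - rois$radius < 1 | rois$y + rois$radius > h))
    stop_invalid("ROI extends outside the frame bounds")
  xs <- matrix(seq_len(w), h, w, byrow = TRUE)
  ys <- matrix(seq_len(h), h, w)
  disk <- lapply(seq_len(n), function(i)
    (xs - rois$x[i])^2 + (ys - rois$y[i])^2 <= rois$radius[i]^2)
  any_disk <- Reduce(`|`, disk)
  ann <- lapply(seq_len(n), function(i) {
    d2 <- (xs - rois$x[i])^2 + (ys - rois$y[i])^2
    ring <- d2 > rois$radius[i]^2 & d2 <= (rois$radius[i] + annulus_width)^2
    ring & !any_disk
  })
  C <- length(frames)
  F <- matrix(0, n, C)
  B <- matrix(0, n, C)
  empty_ann <- vapply(ann, function(m) !any(m), logical(1))
  if (any(empty_ann))
    warning(sprintf("%d ROI(s) have an empty annulus; using the global frame mean",
                    sum(empty_ann)))
  for (k in seq_len(C)) {
    fr <- frames[[k]]
    gm <- mean(fr)
    for (i in seq_len(n)) {
      F[i, k] <- mean(fr[disk[[i]]])
      B[i, k] <- if (empty_ann[i]) gm else mean(fr[ann[[i]]])
    }
  }
  fluor_traces(F, fps, cell_ids = as.character(rois$id), background = B)
}

#' Compute dF/F0 and its time derivative
#'
#' `dff[i, t] = (F[i, t] - F0[i, t]) / F0[i, t]`. The derivative is the
#' first-order forward difference scaled by the frame rate (units 1/s),
#' with the final frame set to zero. Two F0 conventions are supported:
#' the per-cell background recorded with the traces (annulus mean), or a
#' rolling low-percentile of the trace itself for recordings without a
#' background estimate.
#'
#' @param ts a [fluor_traces()].
#' @param f0_mode `"background"` (default; requires `ts$background`) or
#'   `"rolling"` (running `roll_quantile` of F over `roll_window`
#'   seconds).
#' @param max_normalize logical; additionally divide each cell's dff by
#'   its maximum (transient amplitudes normalised to the ROI maximum).
#' @param smooth_frames odd integer >= 3 to apply a boxcar of that many
#'   frames to the derivative; 0 (default) disables smoothing.
#' @param roll_window,roll_quantile rolling-F0 parameters (seconds,
#'   probability).
#' @return object of class `dff_traces`: `dff`, `derivative` (cells x
#'   frames), `fps`, `cell_ids`, `cell_labels`, `f0`.
#' @export
compute_dff <- function(ts, f0_mode = c("background", "rolling"),
                        max_normalize = FALSE, smooth_frames = 0,
                        roll_window = 30, roll_quantile = 0.2) {
  stopifnot(inherits(ts, "fluor_traces"))
  f0_mode <- match.arg(f0_mode)
  F <- ts$F
  n <- nrow(F); C <- ncol(F)
  if (f0_mode == "background") {
    if (is.null(ts$background))
      stop_invalid("trace set has no background; use f0_mode = 'rolling'")
    F0 <- if (is.matrix(ts$background)) ts$background
          else matrix(ts$background, n, C)
  } else {
    W <- max(3L, round(roll_window * ts$fps))
    F0 <- t(vapply(seq_len(n), function(i)
      rolling_quantile(F[i, ], W, roll_quantile), numeric(C)))
  }
  bad <- which(apply(F0 <= 0, 1, any))
  if (length(bad))
    stop_invalid("non-positive F0 for cell(s): %s",
                 paste(ts$cell_ids[bad], collapse = ", "))
  dff <- (F - F0) / F0
  if (max_normalize) {
    mx <- apply(abs(dff), 1, max)
    mx[mx == 0] <- 1
    dff <- dff / mx
  }
  deriv <- cbind(t(apply(dff, 1, diff)) * ts$fps, 0)
  if (n == 1) deriv <- matrix(c(diff(dff[1, ]) * ts$fps, 0), 1, C)
  if (smooth_frames >= 3) {
    k <- rep(1 / smooth_frames, smooth_frames)
    deriv <- t(apply(deriv, 1, function(x)
      stats::filter(x, k, sides = 2) |> (\(y) {y[is.na(y)] <- 0; y})()))
  }
  structure(list(dff = dff, derivative = deriv, fps = ts$fps,
                 cell_ids = ts$cell_ids, cell_labels = ts$cell_labels,
                 f0 = F0),
            class = "dff_traces")
}

# Strided rolling quantile with linear interpolation between anchors;
# window is centred and truncated at the edges.
rolling_quantile <- function(x, W, q, stride = max(1L, W %/% 10L)) {
  C <- length(x)
  anchors <- unique(c(seq(1L, C, by = stride), C))
  vals <- vapply(anchors, function(i) {
    lo <- max(1L, i - W %/% 2L); hi <- min(C, i + W %/% 2L)
    stats::quantile(x[lo:hi], q, names = FALSE)
  }, numeric(1))
  stats::approx(anchors, vals, xout = seq_len(C), rule = 2, ties = "ordered")$y
}

#' Build a dF/F0 trace set directly
#'
#' Convenience constructor for analyses that start from an existing
#' dF/F0 (or derivative) matrix rather than raw fluorescence.
#'
#' @param dff cells x frames matrix of dF/F0.
#' @param fps frame rate, frames/s.
#' @param derivative optional derivative matrix; computed by forward
#'   difference when missing.
#' @param cell_ids,cell_labels as in [fluor_traces()].
#' @return a `dff_traces` object.
#' @export
dff_traces <- function(dff, fps, derivative = NULL, cell_ids = NULL,
                       cell_labels = "unknown") {
  dff <- as.matrix(dff)
  check_positive(fps, "fps")
  n <- nrow(dff); C <- ncol(dff)
  if (is.null(derivative)) {
    derivative <- cbind(t(apply(dff, 1, diff)) * fps, 0)
    if (n == 1) derivative <- matrix(c(diff(dff[1, ]) * fps, 0), 1, C)
  }
  if (!all(dim(derivative) == dim(dff)))
    stop_invalid("derivative dimensions must match dff")
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(n))
  structure(list(dff = dff, derivative = derivative, fps = fps,
                 cell_ids = cell_ids,
                 cell_labels = rep(cell_labels, length.out = n), f0 = NULL),
            class = "dff_traces")
}

#' Infer firing events from the dF/F0 derivative
#'
#' A frame is active when the positive part of d(dF/F0)/dt exceeds
#' `k_sd` baseline standard deviations for that cell (default 2.5).
#'
#' The baseline SD refers to the signal at rest, so the default
#' estimator (`"quiet_mad"`) restricts the robust SD (1.4826 * MAD) of
#' the derivative to quiet frames: frames whose *previous* dF/F0 sample
#' lies below the cell's `quiet_quantile` (dense firing keeps dF/F0
#' elevated, so low-dF/F0 stretches are the inter-event baseline).
#' Conditioning on the previous frame keeps the selection independent of
#' the derivative sample under pure noise, so the estimator stays
#' unbiased there. `"mad"` (full-trace robust SD) and `"sd"` (plain SD)
#' are available for sparse recordings.
#'
#' Runs of consecutive suprathreshold frames are collapsed to their
#' first frame by default, so each calcium transient contributes one
#' event and inter-event intervals are well defined.
#'
#' @param d a `dff_traces` object (see [compute_dff()], [dff_traces()]).
#' @param k_sd threshold in baseline SD units.
#' @param baseline_estimator `"quiet_mad"` (default), `"mad"` or `"sd"`.
#' @param quiet_quantile dF/F0 quantile defining quiet frames for
#'   `"quiet_mad"`.
#' @param collapse logical; collapse suprathreshold runs to one event.
#' @param condition_tag label stored in the raster.
#' @return an [event_raster()].
#' @export
infer_events <- function(d, k_sd = 2.5,
                         baseline_estimator = c("quiet_mad", "mad", "sd"),
                         quiet_quantile = 0.25, collapse = TRUE,
                         condition_tag = "") {
  stopifnot(inherits(d, "dff_traces"))
  baseline_estimator <- match.arg(baseline_estimator)
  deriv <- d$derivative
  n <- nrow(deriv); C <- ncol(deriv)
  if (C < 30) stop_invalid("need at least 30 frames to estimate the baseline SD")
  A <- matrix(0L, n, C)
  dead <- logical(n)
  for (i in seq_len(n)) {
    s <- switch(baseline_estimator,
      quiet_mad = {
        q <- stats::quantile(d$dff[i, ], quiet_quantile, names = FALSE)
        sel <- which(d$dff[i, ] <= q) + 1L   # frame after a quiet sample
        sel <- sel[sel <= C]
        if (length(sel) < 10) stats::mad(deriv[i, ])
        else stats::mad(deriv[i, sel])
      },
      mad = stats::mad(deriv[i, ]),
      sd = stats::sd(deriv[i, ]))
    if (!is.finite(s) || s == 0) { dead[i] <- TRUE; next }
    hit <- deriv[i, ] > k_sd * s
    if (collapse && any(hit)) {
      r <- rle(hit)
      first <- cumsum(c(1L, r$lengths[-length(r$lengths)]))[r$values]
      hit <- logical(C); hit[first] <- TRUE
    }
    A[i, hit] <- 1L
  }
  if (any(dead))
    warning(sprintf("%d cell(s) with zero-variance derivative marked inactive",
                    sum(dead)))
  event_raster(A, d$fps, cell_ids = d$cell_ids, cell_labels = d$cell_labels,
               condition_tag = condition_tag)
}

#' Percentage of active frames per cell
#'
#' Number of active frames divided by the total number of frames,
#' times 100.
#'
#' @param raster an [event_raster()].
#' @return numeric vector, one percentage in `[0, 100]` per cell.
#' @export
percent_active <- function(raster) {
  stopifnot(inherits(raster, "event_raster"))
  if (ncol(raster$A) == 0) stop_invalid("raster has no frames")
  stats::setNames(rowMeans(raster$A) * 100, raster$cell_ids)
}

#' Slice viability filter from the KCl challenge
#'
#' Recordings end with a high-KCl application; a cell is viable when it
#' shows at least one event within that segment, and a slice is kept only
#' when the viable fraction exceeds `min_fraction` (default 0.85).
#'
#' @param raster an [event_raster()] spanning the KCl segment.
#' @param kcl_segment integer frame range `c(first, last)` of the KCl
#'   application.
#' @param min_fraction minimum viable-cell fraction to keep the slice.
#' @return list with `keep` (logical), `fraction`, and per-cell
#'   `responsive` flags.
#' @export
viability_filter <- function(raster, kcl_segment, min_fraction = 0.85) {
  stopifnot(inherits(raster, "event_raster"))
  if (nrow(raster$A) == 0) stop_invalid("raster has no cells")
  ks <- as.integer(kcl_segment)
  if (length(ks) != 2L || ks[1] > ks[2] || ks[1] < 1L || ks[2] > ncol(raster$A))
    stop_invalid("kcl_segment must be a valid, non-empty frame range")
  responsive <- rowSums(raster$A[, ks[1]:ks[2], drop = FALSE]) > 0
  fraction <- mean(responsive)
  list(keep = fraction > min_fraction, fraction = fraction,
       responsive = stats::setNames(responsive, raster$cell_ids))
}
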