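# Core data containers shared by the imaging and ensemble modules.

#' Fluorescence trace set
#'
#' Raw per-ROI fluorescence over frames, with the frame rate and an
#' optional per-cell background (the annulus mean around each ROI, or a
#' scalar), used as F0 when computing dF/F0.
#'
#' @param F numeric matrix, cells x frames, arbitrary fluorescence units
#'   (non-negative).
#' @param fps frame rate, frames per second.
#' @param cell_ids character or integer identifiers, one per row.
#' @param cell_labels `"chat_pos"`, `"chat_neg"` or `"unknown"`, recycled.
#' @param background per-cell background fluorescence: scalar, per-cell
#'   vector, or cells x frames matrix.
#' @return object of class `fluor_traces`.
#' @export
fluor_traces <- function(F, fps, cell_ids = NULL, cell_labels = "unknown",
                         background = NULL) {
  F <- as.matrix(F)
  check_positive(fps, "fps")
  if (any(F < 0)) stop_invalid("fluorescence values must be non-negative")
  n <- nrow(F)
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(n))
  if (length(cell_ids) != n) stop_invalid("cell_ids length must match rows of F")
  cell_labels <- match.arg(rep(cell_labels, length.out = n),
                           c("chat_pos", "chat_neg", "unknown"),
                           several.ok = TRUE)
  if (!is.null(background)) {
    if (is.matrix(background)) {
      if (!all(dim(background) == dim(F)))
        stop_invalid("background matrix dimensions must match F")
    } else {
      background <- rep(as.numeric(background), length.out = n)
    }
  }
  structure(list(F = F, fps = fps, cell_ids = cell_ids,
                 cell_labels = cell_labels, background = background),
            class = "fluor_traces")
}

#' @export
print.fluor_traces <- function(x, ...) {
  cat(sprintf("<fluor_traces> %d cells x %d frames @ %.1f fps\n",
              nrow(x$F), ncol(x$F), x$fps))
  invisible(x)
}

#' Binary event raster
#'
#' Activity matrix of inferred firing: R cells (rows) x C frames
#' (columns), ones at frames where activity was detected.
#'
#' @param A binary matrix (0/1 or logical), cells x frames.
#' @param fps frame rate, frames per second.
#' @param cell_ids,cell_labels as in [fluor_traces()].
#' @param condition_tag free-form label for the experimental condition
#'   (e.g. `"control"`, `"DA_depleted"`, `"+CNQX+APV"`).
#' @return object of class `event_raster`.
#' @export
event_raster <- function(A, fps, cell_ids = NULL, cell_labels = "unknown",
                         condition_tag = "") {
  A <- as.matrix(A)
  storage.mode(A) <- "integer"
  if (!all(A %in% c(0L, 1L))) stop_invalid("raster entries must be 0 or 1")
  check_positive(fps, "fps")
  n <- nrow(A)
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(n))
  if (length(cell_ids) != n) stop_invalid("cell_ids length must match rows of A")
  cell_labels <- match.arg(rep(cell_labels, length.out = n),
                           c("chat_pos", "chat_neg", "unknown"),
                           several.ok = TRUE)
  structure(list(A = A, fps = fps, cell_ids = cell_ids,
                 cell_labels = cell_labels, condition_tag = condition_tag),
            class = "event_raster")
}

#' @export
print.event_raster <- function(x, ...) {
  cat(sprintf("<event_raster> %d cells x %d frames @ %.1f fps, %d events%s\n",
              nrow(x$A), ncol(x$A), x$fps, sum(x$A),
              if (nzchar(x$condition_tag)) paste0(" [", x$condition_tag, "]") else ""))
  invisible(x)
}

#' Current-clamp sweep recording
#'
#' @param t time, seconds (uniformly sampled).
#' @param V membrane voltage, mV.
#' @param I injected current, pA: either a vector the length of `t` or a
#'   scalar holding current (the step descriptor then carries the pulse).
#' @param fs sampling rate, Hz. Inferred from `t` when missing.
#' @param step optional list `(amplitude, t_on, t_off)` describing a
#'   current step, pA / s / s.
#' @param spike_times optional ground-truth spike times, seconds.
#' @return object of class `sweep_recording`.
#' @export
sweep_recording <- function(t, V, I = 0, fs = NULL, step = NULL,
                            spike_times = NULL) {
  if (length(t) != length(V)) stop_invalid("t and V must have equal length")
  if (is.null(fs)) fs <- 1 / stats::median(diff(t))
  if (length(I) == 1L) I <- rep(I, length(t))
  if (length(I) != length(t)) stop_invalid("I must be scalar or match t")
  structure(list(t = t, V = V, I = I, fs = fs, step = step,
                 spike_times = spike_times),
            class = "sweep_recording")
}

#' @export
print.sweep_recording <- function(x, ...) {
  cat(sprintf("<sweep_recording> %.2f s @ %.0f Hz", max(x$t) - min(x$t), x$fs))
  if (!is.null(x$step))
    cat(sprintf(", step %+.0f pA [%.2f, %.2f] s", x$step$amplitude,
                x$step$t_on, x$step$t_off))
  cat("\n")
  invisible(x)
}
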