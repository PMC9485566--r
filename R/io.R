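# Plain-text interchange: trace tables (rows = cells, columns = frames,
# header row of frame times) with a JSON sidecar, 0/1 raster CSVs with
# JSON metadata, and sweep CSVs (time_s, voltage_mV, current_pA) with a
# protocol JSON.

#' Write / read fluorescence traces as CSV + JSON sidecar
#'
#' @param ts a [fluor_traces()].
#' @param path CSV path; the sidecar is written at `<path>.json`.
#' @return invisibly, `path`.
#' @export
write_traces <- function(ts, path) {
  stopifnot(inherits(ts, "fluor_traces"))
  m <- as.data.frame(ts$F)
  names(m) <- sprintf("t%.4f", (seq_len(ncol(ts$F)) - 1) / ts$fps)
  out <- cbind(data.frame(cell_id = ts$cell_ids, label = ts$cell_labels), m)
  utils::write.csv(out, path, row.names = FALSE)
  meta <- list(fps = ts$fps,
               background = if (is.matrix(ts$background)) "matrix"
                            else ts$background)
  if (is.matrix(ts$background)) {
    utils::write.csv(as.data.frame(ts$background),
                     paste0(path, ".background.csv"), row.names = FALSE)
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  F <- as.matrix(df[, -(1:2), drop = FALSE])
  dimnames(F) <- NULL
  bg <- meta$background
  if (identical(bg, "matrix")) {
    bg <- as.matrix(utils::read.csv(paste0(path, ".background.csv")))
    dimnames(bg) <- NULL
  }
  fluor_traces(F, fps = meta$fps, cell_ids = df$cell_id,
               cell_labels = df$label, background = bg)
}

#' Write / read an event raster as CSV + JSON metadata
#'
#' @param raster an [event_raster()].
#' @param path CSV path; metadata goes to `<path>.json`.
#' @param params optional named list of analysis parameters to log in
#'   the metadata (e.g. `k_sd`, estimator).
#' @return invisibly, `path`.
#' @export
write_raster <- function(raster, path, params = list()) {
  stopifnot(inherits(raster, "event_raster"))
  out <- cbind(data.frame(cell_id = raster$cell_ids,
                          label = raster$cell_labels),
               as.data.frame(raster$A))
  utils::write.csv(out, path, row.names = FALSE)
  meta <- c(list(fps = raster$fps, condition_tag = raster$condition_tag),
            params)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  A <- as.matrix(df[, -(1:2), drop = FALSE])
  dimnames(A) <- NULL
  event_raster(A, fps = meta$fps, cell_ids = df$cell_id,
               cell_labels = df$label,
               condition_tag = meta$condition_tag %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a current-clamp sweep as CSV + protocol JSON
#'
#' @param sweep a [sweep_recording()].
#' @param path CSV path (`time_s, voltage_mV, current_pA`); the step
#'   protocol goes to `<path>.json`.
#' @return invisibly, `path`.
#' @export
write_sweep <- function(sweep, path) {
  stopifnot(inherits(sweep, "sweep_recording"))
  utils::write.csv(data.frame(time_s = sweep$t, voltage_mV = sweep$V,
                              current_pA = sweep$I),
                   path, row.names = FALSE)
  jsonlite::write_json(list(fs = sweep$fs, step = sweep$step,
                            spike_times = sweep$spike_times),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sweep
#' @export
read_sweep <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  step <- if (!is.null(meta$step)) as.list(meta$step) else NULL
  sweep_recording(df$time_s, df$voltage_mV, df$current_pA, fs = meta$fs,
                  step = step, spike_times = meta$spike_times)
}
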