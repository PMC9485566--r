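# Publication-style figures: raster + coactivity panels, activity CDFs,
# I-V curves and phase plots. Base graphics, one panel per call.

#' Raster plot with coactivity histogram
#'
#' Rows are cells (dots at active frames), the lower panel shows the
#' frame-wise coactivity with the Monte-Carlo significance threshold as
#' a dashed line when a profile is supplied.
#'
#' @param x an [event_raster()].
#' @param profile optional `coactivity_profile` from [mc_threshold()].
#' @param ... further arguments passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @export
plot.event_raster <- function(x, profile = NULL, ...) {
  A <- x$A
  R <- nrow(A); C <- ncol(A)
  tt <- (seq_len(C) - 1) / x$fps
  op <- graphics::par(mfrow = c(2, 1), mar = c(1, 4, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  graphics::plot(NA, xlim = range(tt), ylim = c(0.5, R + 0.5), xaxt = "n",
                 xlab = "", ylab = "cell",
                 main = if (nzchar(x$condition_tag)) x$condition_tag else "raster", ...)
  for (i in seq_len(R)) {
    f <- which(A[i, ] == 1L)
    if (length(f)) graphics::points(tt[f], rep(i, length(f)), pch = 16, cex = 0.3,
                                    col = if (x$cell_labels[i] == "chat_pos") "blue3" else "grey40")
  }
  graphics::par(mar = c(4, 4, 0.5, 1))
  counts <- colSums(A)
  graphics::plot(tt, counts, type = "h", xlab = "time (s)", ylab = "coactivity")
  if (!is.null(profile) && !is.na(profile$threshold))
    graphics::abline(h = profile$threshold, lty = 2, col = "red3")
  invisible(x)
}

#' Empirical CDFs of per-neuron activity by condition
#'
#' @param x a `cdf_comparison_set` from [activity_cdf()].
#' @param ... further arguments passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @export
plot.cdf_comparison_set <- function(x, ...) {
  cols <- grDevices::hcl.colors(max(3, length(x$samples)), "Dark 3")
  rng <- range(unlist(x$samples))
  graphics::plot(NA, xlim = rng, ylim = c(0, 1),
                 xlab = "% active frames", ylab = "cumulative probability", ...)
  for (i in seq_along(x$samples))
    graphics::lines(stats::ecdf(x$samples[[i]]), col = cols[i], do.points = FALSE)
  graphics::legend("bottomright", legend = names(x$samples), col = cols,
                   lty = 1, bty = "n")
  invisible(x)
}

#' @export
plot.iv_curve <- function(x, ...) {
  graphics::plot(x$points$I, x$points$V, pch = 16,
                 xlab = "I (pA)", ylab = "V (mV)", ...)
  b <- x$cubic_coeffs
  ii <- seq(min(x$points$I), max(x$points$I), length.out = 200)
  graphics::lines(ii, b[1] + b[2] * ii + b[3] * ii^2 + b[4] * ii^3, col = "red3")
  graphics::abline(h = x$eval_point, lty = 3)
  invisible(x)
}

#' @export
plot.phase_plot <- function(x, ...) {
  a <- x$average
  graphics::plot(a$V, a$dvdt, type = "l",
                 xlab = "V (mV)", ylab = "dV/dt (mV/ms)", ...)
  if (any(a$dvdt_sem > 0)) {
    graphics::lines(a$V, a$dvdt + a$dvdt_sem, col = "grey60")
    graphics::lines(a$V, a$dvdt - a$dvdt_sem, col = "grey60")
  }
  invisible(x)
}
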