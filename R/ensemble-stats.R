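# Population statistics on event rasters: frame-wise coactivity with a
# Monte-Carlo surrogate significance threshold, rate of activity
# accumulation, inter-event intervals, and activity CDFs.

#' Frame-wise coactivity counts
#'
#' Column sums of the raster: how many cells are active in each frame.
#'
#' @param raster an [event_raster()].
#' @return integer vector of length C (frames).
#' @export
coactivity <- function(raster) {
  stopifnot(inherits(raster, "event_raster"))
  as.integer(colSums(raster$A))
}

#' Monte-Carlo significance threshold for coactivity peaks
#'
#' Builds a surrogate null by independently circular-shifting each
#' cell's event row (preserving per-cell event counts and within-cell
#' interval structure) or by permuting each cell's event frames, and
#' pools the surrogate frame-coactivity distribution. The significance
#' threshold is the smallest count `c` whose pooled surrogate tail
#' probability `P(count >= c)` is below `alpha` - the dashed line drawn
#' under population rasters. Frames at or above the threshold are
#' flagged significant.
#'
#' @param raster an [event_raster()] with at least 2 cells and 2 frames.
#' @param n_surrogates number of surrogate rasters.
#' @param alpha significance level.
#' @param method `"circular_shift"` (default) or `"permute"`.
#' @param seed integer seed for the surrogate draws.
#' @return object of class `coactivity_profile`: `counts`, `threshold`,
#'   `significant_frames`, `n_sig_frames`, `n_sig_peaks` (runs of
#'   adjacent significant frames counted once),
#'   `expected_chance_frames` (frames expected at or above the
#'   threshold under the surrogate null itself), `n_excess_frames`
#'   (observed minus chance - the above-chance coactivity load),
#'   `surrogate_dist` (pooled probabilities of counts `0..R`), plus the
#'   call parameters.
#'   A raster with no events yields an empty profile (`threshold = NA`).
#' @export
mc_threshold <- function(raster, n_surrogates = 1000, alpha = 0.05,
                         method = c("circular_shift", "permute"), seed = NULL) {
  stopifnot(inherits(raster, "event_raster"))
  method <- match.arg(method)
  A <- raster$A
  R <- nrow(A); C <- ncol(A)
  if (R < 2) stop_invalid("need at least 2 cells")
  if (C < 2) stop_invalid("need at least 2 frames")
  counts <- as.integer(colSums(A))
  ev <- lapply(seq_len(R), function(i) which(A[i, ] == 1L))
  n_ev <- lengths(ev)
  if (sum(n_ev) == 0L) {
    warning("raster has no events; threshold undefined")
    return(structure(list(counts = counts, threshold = NA_integer_,
                          significant_frames = rep(FALSE, C),
                          n_sig_frames = 0L, n_sig_peaks = 0L,
                          expected_chance_frames = 0, n_excess_frames = 0,
                          surrogate_dist = c(`0` = 1, stats::setNames(rep(0, R), seq_len(R))),
                          alpha = alpha, n_surrogates = n_surrogates,
                          method = method, seed = seed),
                     class = "coactivity_profile"))
  }
  pos <- unlist(ev)                       # event frame per event
  cell_of <- rep.int(seq_len(R), n_ev)    # owning cell per event
  dist <- numeric(R + 1)                  # frequencies of counts 0..R
  with_seed(seed, {
    for (b in seq_len(n_surrogates)) {
      if (method == "circular_shift") {
        shift <- sample.int(C, R, replace = TRUE) - 1L
        newpos <- (pos - 1L + shift[cell_of]) %% C + 1L
      } else {
        newpos <- unlist(lapply(seq_len(R), function(i)
          if (n_ev[i]) sample.int(C, n_ev[i]) else integer(0)))
      }
      tb <- tabulate(newpos, C)
      dist <- dist + tabulate(tb + 1L, R + 1L)
    }
  })
  p <- dist / sum(dist)
  tail_p <- rev(cumsum(rev(p)))           # P(count >= c), c = 0..R
  ok <- which(tail_p[-1] < alpha)         # candidate thresholds c = 1..R
  threshold <- if (length(ok)) min(ok) else R + 1L
  sig <- counts >= threshold
  runs <- rle(sig)
  # chance level: expected number of flagged frames if the raster obeyed
  # its own surrogate null (the discrete threshold can land well below
  # alpha, so the observed count is only meaningful relative to this)
  expected_chance <- if (threshold <= R) C * tail_p[threshold + 1L] else 0
  structure(list(counts = counts, threshold = as.integer(threshold),
                 significant_frames = sig,
                 n_sig_frames = sum(sig),
                 n_sig_peaks = sum(runs$values),
                 expected_chance_frames = expected_chance,
                 n_excess_frames = sum(sig) - expected_chance,
                 surrogate_dist = stats::setNames(p, 0:R),
                 alpha = alpha, n_surrogates = n_surrogates,
                 method = method, seed = seed),
            class = "coactivity_profile")
}

#' @export
print.coactivity_profile <- function(x, ...) {
  cat(sprintf("<coactivity_profile> %d frames, threshold = %s (alpha %.3g), %d significant frames in %d peaks\n",
              length(x$counts), x$threshold, x$alpha, x$n_sig_frames,
              x$n_sig_peaks))
  invisible(x)
}

#' Rate of activity accumulation
#'
#' Running sum of the coactivity counts over frames, with an ordinary
#' least-squares line fitted to the cumulative curve against the frame
#' index. The slope (events/frame, also reported events/s) is the rate
#' of activity accumulation used to compare conditions.
#'
#' @param counts per-frame coactivity counts (or an [event_raster()],
#'   whose coactivity is taken).
#' @param fps frame rate for the events/s conversion; taken from the
#'   raster when one is supplied.
#' @param window optional frame range `c(first, last)` to restrict the
#'   fit (e.g. a drug wash-in segment).
#' @return object of class `accumulation_fit`: `slope` (events/frame),
#'   `slope_per_s`, `intercept`, `r_squared`, `cumulative`.
#' @export
accumulation_slope <- function(counts, fps = NULL, window = NULL) {
  if (inherits(counts, "event_raster")) {
    if (is.null(fps)) fps <- counts$fps
    counts <- coactivity(counts)
  }
  counts <- as.numeric(counts)
  if (!is.null(window)) counts <- counts[window[1]:window[2]]
  C <- length(counts)
  if (C < 2) stop_invalid("need at least 2 frames")
  cum <- cumsum(counts)
  x <- seq_len(C) - 1
  mx <- mean(x); my <- mean(cum)
  sxx <- sum((x - mx)^2)
  slope <- sum((x - mx) * (cum - my)) / sxx
  intercept <- my - slope * mx
  ss_res <- sum((cum - intercept - slope * x)^2)
  ss_tot <- sum((cum - my)^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(list(slope = slope,
                 slope_per_s = if (is.null(fps)) NA_real_ else slope * fps,
                 intercept = intercept, r_squared = r2, cumulative = cum),
            class = "accumulation_fit")
}

#' @export
print.accumulation_fit <- function(x, ...) {
  cat(sprintf("<accumulation_fit> slope = %.4g events/frame (%.4g events/s), r^2 = %.4f\n",
              x$slope, x$slope_per_s, x$r_squared))
  invisible(x)
}

#' Inter-event intervals of a raster
#'
#' Successive differences of each cell's event frame times, in seconds
#' (inferred interspike intervals). Cells with fewer than two events
#' contribute nothing. Intended for collapsed rasters (one event per
#' transient).
#'
#' @param raster an [event_raster()].
#' @return object of class `interval_set`: `per_cell` (list of numeric
#'   vectors), `pooled`, `condition_tag`.
#' @export
iisi_extract <- function(raster) {
  stopifnot(inherits(raster, "event_raster"))
  per_cell <- lapply(seq_len(nrow(raster$A)), function(i) {
    f <- which(raster$A[i, ] == 1L)
    if (length(f) < 2) numeric(0) else diff(f) / raster$fps
  })
  names(per_cell) <- raster$cell_ids
  structure(list(per_cell = per_cell, pooled = unlist(per_cell, use.names = FALSE),
                 condition_tag = raster$condition_tag),
            class = "interval_set")
}

#' Multi-scale interval histograms and pooled CDF
#'
#' The interval distribution is heavily skewed, so it is binned at three
#' scales: short intervals (< 1 s, ongoing firing), intermediate pauses
#' (1-60 s, silences between spike trains), and long silences
#' (60-120 s). Intervals beyond the last scale are counted in
#' `n_overflow`. The pooled empirical CDF covers all intervals.
#'
#' @param intervals an `interval_set` (see [iisi_extract()]) or numeric
#'   vector of intervals in seconds.
#' @param breaks_short,breaks_mid,breaks_long bin edges for the three
#'   scales, seconds.
#' @return list with the three histogram objects (`counts`, `breaks`),
#'   scale totals, `n_overflow`, and `cdf` (an [stats::ecdf()] of all
#'   intervals).
#' @export
iisi_histograms <- function(intervals,
                            breaks_short = seq(0, 1, by = 0.1),
                            breaks_mid = c(1, seq(5, 60, by = 5)),
                            breaks_long = seq(60, 120, by = 10)) {
  iv <- if (inherits(intervals, "interval_set")) intervals$pooled
        else as.numeric(intervals)
  if (!length(iv)) stop_invalid("no intervals supplied")
  pick <- function(lo, hi) iv[iv >= lo & iv < hi]
  h <- function(x, breaks) {
    if (!length(x)) return(list(counts = integer(length(breaks) - 1), breaks = breaks))
    hh <- graphics::hist(x, breaks = breaks, plot = FALSE, right = FALSE)
    list(counts = hh$counts, breaks = breaks)
  }
  short <- pick(0, breaks_short[length(breaks_short)])
  mid <- pick(breaks_mid[1], breaks_mid[length(breaks_mid)])
  long <- pick(breaks_long[1], breaks_long[length(breaks_long)])
  list(short = h(short, breaks_short),
       mid = h(mid, breaks_mid),
       long = h(long, breaks_long),
       totals = c(short = length(short), mid = length(mid), long = length(long)),
       n_overflow = sum(iv >= breaks_long[length(breaks_long)]),
       cdf = stats::ecdf(iv))
}

#' Compare per-condition activity distributions (CDFs)
#'
#' Pools per-neuron percent-active values across experiments for each
#' condition and runs a two-sample Kolmogorov-Smirnov test per planned
#' comparison, with a Bonferroni-adjusted alpha for the family.
#'
#' @param groups named list; each element is either a numeric vector of
#'   per-neuron percentages or a list of [event_raster()]s whose
#'   [percent_active()] values are pooled.
#' @param comparisons list of 2-element character vectors naming the
#'   planned comparisons; default all pairs.
#' @param alpha family-wise significance level.
#' @return list of class `cdf_comparison_set`: one entry per comparison
#'   with `ks_D`, `p_value`, `n_a`, `n_b`, `bonferroni_alpha`,
#'   `significant`, plus the pooled `samples`.
#' @export
activity_cdf <- function(groups, comparisons = NULL, alpha = 0.05) {
  pool <- lapply(groups, function(g) {
    if (is.numeric(g)) g
    else if (inherits(g, "event_raster")) as.numeric(percent_active(g))
    else unlist(lapply(g, function(r) as.numeric(percent_active(r))))
  })
  bad <- names(pool)[vapply(pool, length, integer(1)) < 2]
  if (length(bad))
    stop_invalid("group(s) with fewer than 2 neurons: %s",
                 paste(bad, collapse = ", "))
  if (is.null(comparisons)) {
    comparisons <- utils::combn(names(pool), 2, simplify = FALSE)
  }
  bonf <- alpha / length(comparisons)
  res <- lapply(comparisons, function(cp) {
    a <- pool[[cp[1]]]; b <- pool[[cp[2]]]
    kt <- suppressWarnings(stats::ks.test(a, b))
    list(comparison = cp, ks_D = unname(kt$statistic),
         p_value = kt$p.value, n_a = length(a), n_b = length(b),
         bonferroni_alpha = bonf, significant = kt$p.value < bonf)
  })
  names(res) <- vapply(comparisons, paste, character(1), collapse = " vs ")
  structure(list(comparisons = res, samples = pool, alpha = alpha,
                 bonferroni_alpha = bonf),
            class = "cdf_comparison_set")
}

#' @export
print.cdf_comparison_set <- function(x, ...) {
  cat(sprintf("<cdf_comparison_set> %d comparison(s), Bonferroni alpha = %.4g\n",
              length(x$comparisons), x$bonferroni_alpha))
  for (cc in x$comparisons)
    cat(sprintf("  %-40s D = %.3f, p = %.3g (n = %d, %d)%s\n",
                paste(cc$comparison, collapse = " vs "), cc$ks_D, cc$p_value,
                cc$n_a, cc$n_b, if (cc$significant) " *" else ""))
  invisible(x)
}
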