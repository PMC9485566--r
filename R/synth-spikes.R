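# Synthetic spike trains: gamma-renewal tonic/irregular firing and an
# alternating burst/pause two-state process, emulating the autonomous
# firing regimes of striatal cholinergic interneurons (tonic or irregular
# single-spike firing at 2-10 Hz, and bursts interspersed with pauses).

#' Generate a synthetic spike train
#'
#' Tonic and irregular trains are gamma-renewal processes: inter-spike
#' intervals are i.i.d. gamma with mean `1/rate` and coefficient of
#' variation `cv` (gamma shape `1/cv^2`; `cv = 0` gives a perfectly
#' periodic train, `cv = 1` a Poisson train). The `burst_pause` pattern
#' alternates exponentially distributed burst and pause states; bursts
#' fire as a high-rate gamma-renewal process and pauses are silent, with
#' the within-burst rate scaled so the long-run mean rate equals `rate`.
#'
#' @param pattern one of `"tonic"`, `"irregular"`, `"burst_pause"`.
#' @param rate requested long-run mean firing rate, Hz.
#' @param cv coefficient of variation of inter-spike intervals. Defaults:
#'   0.05 for `"tonic"`, 1 for `"irregular"`; for `"burst_pause"` this is
#'   the within-burst CV (default 0.2).
#' @param duration recording length, seconds.
#' @param seed integer seed; identical seeds give identical trains.
#' @param burst_len,pause_len mean burst and pause durations, seconds
#'   (`burst_pause` only).
#' @param burst_rate within-burst firing rate, Hz. Default scales `rate`
#'   by the burst duty cycle so the overall mean rate is preserved.
#' @return an object of class `spike_train`: a list with `spike_times`
#'   (strictly increasing, within `[0, duration]`), `duration`,
#'   `pattern` and `params`.
#' @examples
#' st <- make_spike_train("tonic", rate = 2, cv = 0, duration = 10, seed = 1)
#' length(st$spike_times)  # 20 spikes, all ISIs 0.5 s
#' @export
make_spike_train <- function(pattern = c("tonic", "irregular", "burst_pause"),
                             rate, cv = NULL, duration, seed = NULL,
                             burst_len = 1, pause_len = 2, burst_rate = NULL) {
  pattern <- match.arg(pattern)
  check_positive(rate, "rate")
  check_positive(duration, "duration")
  if (is.null(cv)) {
    cv <- switch(pattern, tonic = 0.05, irregular = 1, burst_pause = 0.2)
  }
  check_nonneg(cv, "cv")

  times <- with_seed(seed, {
    if (pattern == "burst_pause") {
      check_positive(burst_len, "burst_len")
      check_positive(pause_len, "pause_len")
      if (is.null(burst_rate)) {
        burst_rate <- rate * (burst_len + pause_len) / burst_len
      }
      check_positive(burst_rate, "burst_rate")
      burst_pause_times(burst_rate, cv, burst_len, pause_len, duration)
    } else {
      renewal_times(rate, cv, duration)
    }
  })

  structure(list(
    spike_times = times,
    duration = duration,
    pattern = pattern,
    params = list(rate = rate, cv = cv, seed = seed,
                  burst_len = if (pattern == "burst_pause") burst_len else NULL,
                  pause_len = if (pattern == "burst_pause") pause_len else NULL,
                  burst_rate = if (pattern == "burst_pause") burst_rate else NULL)
  ), class = "spike_train")
}

# Ordinary gamma-renewal process started at t = 0 (first spike after the
# first interval). cv = 0 degenerates to a periodic train.
renewal_times <- function(rate, cv, duration, t0 = 0) {
  horizon <- duration - t0
  if (horizon <= 0) return(numeric(0))
  n_guess <- ceiling(horizon * rate + 4 * sqrt(horizon * rate + 1) + 10)
  draw <- function(n) {
    if (cv == 0) rep(1 / rate, n)
    else {
      shape <- 1 / cv^2
      stats::rgamma(n, shape = shape, rate = shape * rate)
    }
  }
  isi <- draw(n_guess)
  t <- t0 + cumsum(isi)
  while (sum(isi) < horizon) {
    isi2 <- draw(n_guess)
    t <- c(t, t[length(t)] + cumsum(isi2))
    isi <- c(isi, isi2)
  }
  t[t <= duration + 1e-9]
}

burst_pause_times <- function(burst_rate, cv, burst_len, pause_len, duration) {
  # Stationary start: probability of beginning inside a burst equals the
  # burst duty cycle.
  in_burst <- stats::runif(1) < burst_len / (burst_len + pause_len)
  t <- 0
  out <- list()
  while (t < duration) {
    seg <- stats::rexp(1, 1 / if (in_burst) burst_len else pause_len)
    seg_end <- min(t + seg, duration)
    if (in_burst) {
      s <- renewal_times(burst_rate, cv, seg_end - t)
      if (length(s)) out[[length(out) + 1L]] <- t + s
    }
    t <- t + seg
    in_burst <- !in_burst
  }
  ts <- unlist(out)
  ts[ts <= duration + 1e-9]
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> pattern=%s  %d spikes over %.1f s (%.2f Hz)\n",
              x$pattern, length(x$spike_times), x$duration,
              length(x$spike_times) / x$duration))
  invisible(x)
}
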