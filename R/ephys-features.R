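# Current-clamp feature battery: spike detection, cubic I-V fits and
# input resistance, rheobase, sag ratio, phase plots (dV/dt vs V), AP
# waveform features with indentation classification, AHP half-width,
# firing statistics, and intensity-frequency curves.

# Centered-difference dV/dt in mV/ms from a sampled voltage trace.
dvdt_trace <- function(V, fs) {
  n <- length(V)
  d <- numeric(n)
  if (n >= 3) d[2:(n - 1)] <- (V[3:n] - V[1:(n - 2)]) * fs / 2000
  d[1] <- (V[2] - V[1]) * fs / 1000
  d[n] <- (V[n] - V[n - 1]) * fs / 1000
  d
}

#' Detect action potentials in a sweep
#'
#' One detection per AP, placed at the upward crossing of dV/dt through
#' `dvdt_crossing`, with a refractory lockout.
#'
#' @param sweep a [sweep_recording()] (or a numeric voltage vector with
#'   `fs` supplied).
#' @param dvdt_crossing detection threshold, mV/ms.
#' @param refractory_ms lockout after each detection, ms.
#' @param fs sampling rate when `sweep` is a plain vector, Hz.
#' @return numeric vector of spike times, seconds.
#' @export
detect_spikes <- function(sweep, dvdt_crossing = 10, refractory_ms = 2,
                          fs = NULL) {
  if (inherits(sweep, "sweep_recording")) {
    V <- sweep$V; fs <- sweep$fs; t <- sweep$t
  } else {
    V <- as.numeric(sweep)
    if (is.null(fs)) stop_invalid("fs required for a plain voltage vector")
    t <- (seq_along(V) - 1) / fs
  }
  d <- dvdt_trace(V, fs)
  up <- which(d[-1] >= dvdt_crossing & d[-length(d)] < dvdt_crossing) + 1L
  if (!length(up)) return(numeric(0))
  keep <- numeric(0)
  last <- -Inf
  gap <- refractory_ms / 1000
  for (i in up) {
    if (t[i] - last >= gap) { keep <- c(keep, i); last <- t[i] }
  }
  t[keep]
}

#' Fit a cubic I-V relationship and read off the input resistance
#'
#' Steady-state voltages across step amplitudes are non-linear in the
#' current, so a third-order polynomial V(I) is fitted and the input
#' resistance R_N is the slope dV/dI of the cubic, evaluated at the
#' membrane potential `eval_at` (in MOhm; mV per pA times 1000).
#'
#' @param iv either a data.frame with columns `I` (pA) and `V` (mV,
#'   steady state), or a list of [sweep_recording()]s with step
#'   descriptors, from which steady-state voltages are measured as the
#'   mean over the last `ss_window` seconds of each step.
#' @param eval_at membrane potential at which R_N is evaluated, mV.
#' @param ss_window steady-state window, seconds.
#' @return object of class `iv_curve`: `points`, `cubic_coeffs`
#'   (intercept first), `R_N` (MOhm), `eval_point` (mV), `eval_I` (pA).
#' @export
fit_iv <- function(iv, eval_at = -60, ss_window = 0.1) {
  if (!is.data.frame(iv)) {
    sweeps <- iv
    if (any(vapply(sweeps, function(s) length(s$spike_times) > 0, logical(1))))
      sweeps <- Filter(function(s) length(s$spike_times) == 0, sweeps)
    if (length(sweeps) < 4)
      stop_invalid("need at least 4 subthreshold sweeps to fit a cubic")
    iv <- do.call(rbind, lapply(sweeps, function(s) {
      sel <- s$t >= s$step$t_off - ss_window & s$t < s$step$t_off
      data.frame(I = s$step$amplitude, V = mean(s$V[sel]))
    }))
  }
  if (nrow(iv) < 4) stop_invalid("need at least 4 (I, V) points to fit a cubic")
  fit <- stats::lm(V ~ I + I2 + I3,
                   data = data.frame(V = iv$V, I = iv$I, I2 = iv$I^2, I3 = iv$I^3))
  b <- unname(stats::coef(fit))
  vfun <- function(I) b[1] + b[2] * I + b[3] * I^2 + b[4] * I^3
  dfun <- function(I) b[2] + 2 * b[3] * I + 3 * b[4] * I^2
  rng <- range(iv$I)
  f <- function(I) vfun(I) - eval_at
  eval_I <- if (f(rng[1]) * f(rng[2]) <= 0) {
    stats::uniroot(f, interval = rng, tol = 1e-10)$root
  } else {
    warning(sprintf("V = %g mV not bracketed by the fitted I-V range; using the nearest point", eval_at))
    iv$I[which.min(abs(iv$V - eval_at))]
  }
  structure(list(points = iv[order(iv$I), ], cubic_coeffs = b,
                 R_N = dfun(eval_I) * 1000, eval_point = eval_at,
                 eval_I = eval_I),
            class = "iv_curve")
}

#' @export
print.iv_curve <- function(x, ...) {
  cat(sprintf("<iv_curve> %d points, R_N = %.1f MOhm at %g mV\n",
              nrow(x$points), x$R_N, x$eval_point))
  invisible(x)
}

#' Rheobase: minimum step current evoking an action potential
#'
#' Runs 1-s current steps over an ascending amplitude grid and returns
#' the smallest amplitude that evokes at least one spike.
#'
#' @param ms a [membrane_scenario()], or a list of [sweep_recording()]s
#'   (with step descriptors) already simulated/recorded.
#' @param amplitudes ascending amplitude grid, pA.
#' @param duration step duration, seconds.
#' @param fs sampling rate for simulation, Hz.
#' @return list with `rheobase` (pA), `step_pA` (grid resolution),
#'   `n_spikes_at_rheobase`.
#' @export
rheobase <- function(ms, amplitudes = seq(5, 300, by = 5), duration = 1,
                     fs = 10000) {
  count_spikes <- function(sw) {
    st <- sw$spike_times
    if (is.null(st)) st <- detect_spikes(sw)
    sum(st >= sw$step$t_on & st < sw$step$t_off)
  }
  if (inherits(ms, "membrane_scenario")) {
    amplitudes <- sort(amplitudes)
    for (a in amplitudes) {
      sw <- simulate_current_step(ms, a, t_on = 0.1, t_off = 0.1 + duration,
                                  fs = fs)
      if (count_spikes(sw) >= 1)
        return(list(rheobase = a, step_pA = min(diff(amplitudes)),
                    n_spikes_at_rheobase = count_spikes(sw)))
    }
    stop_invalid("no spiking amplitude found up to %g pA", max(amplitudes))
  }
  sweeps <- ms[order(vapply(ms, function(s) s$step$amplitude, numeric(1)))]
  for (sw in sweeps) {
    if (count_spikes(sw) >= 1) {
      amps <- vapply(sweeps, function(s) s$step$amplitude, numeric(1))
      return(list(rheobase = sw$step$amplitude,
                  step_pA = min(diff(sort(amps))),
                  n_spikes_at_rheobase = count_spikes(sw)))
    }
  }
  stop_invalid("no sweep evoked a spike (max tested %g pA)",
               max(vapply(ms, function(s) s$step$amplitude, numeric(1))))
}

#' Sag ratio of a hyperpolarizing step response
#'
#' Peak early deflection divided by the late (steady) deflection during
#' a hyperpolarizing current step; values above 1 indicate an
#' HCN-mediated sag. The peak is searched in the first `early_window`
#' seconds of the step and the steady level is the mean over the last
#' `late_window` seconds.
#'
#' @param sweep a [sweep_recording()] with a hyperpolarizing step
#'   descriptor.
#' @param early_window,late_window window lengths, seconds.
#' @param baseline_window pre-step window used for the baseline, seconds.
#' @param min_deflection minimum steady deflection, mV.
#' @return the sag ratio (dimensionless).
#' @export
sag_ratio <- function(sweep, early_window = 0.2, late_window = 0.1,
                      baseline_window = 0.1, min_deflection = 2) {
  stopifnot(inherits(sweep, "sweep_recording"))
  st <- sweep$step
  if (is.null(st)) stop_invalid("sweep carries no step descriptor")
  if (st$amplitude >= 0) stop_invalid("sag ratio requires a hyperpolarizing step")
  t <- sweep$t; V <- sweep$V
  base <- mean(V[t >= st$t_on - baseline_window & t < st$t_on])
  early <- t >= st$t_on & t < st$t_on + early_window
  late <- t >= st$t_off - late_window & t < st$t_off
  peak <- max(base - V[early])
  steady <- mean(base - V[late])
  if (steady < min_deflection)
    stop_invalid("steady deflection %.2f mV below the %.1f mV minimum",
                 steady, min_deflection)
  peak / steady
}

#' Phase-plot (dV/dt vs V) curves per spike
#'
#' Extracts a voltage window around each spike and pairs the voltage
#' with its centered-difference derivative, optionally averaging curves
#' across spikes on a common time grid (mean +/- SEM).
#'
#' @param sweep a [sweep_recording()] or numeric voltage vector.
#' @param fs sampling rate when a plain vector is given, Hz.
#' @param spike_times spike anchor times, seconds; detected when `NULL`.
#' @param window_ms window around each spike peak `c(before, after)`, ms.
#' @return object of class `phase_plot`: `spikes` (list of data.frames
#'   `t_ms, V, dvdt`), and `average` (data.frame `t_ms, V, V_sem, dvdt,
#'   dvdt_sem`) when at least one spike is complete.
#' @export
phase_plot <- function(sweep, fs = NULL, spike_times = NULL,
                       window_ms = c(3, 12)) {
  if (inherits(sweep, "sweep_recording")) {
    V <- sweep$V; fs <- sweep$fs
  } else {
    V <- as.numeric(sweep)
    if (is.null(fs)) stop_invalid("fs required for a plain voltage vector")
  }
  if (is.null(spike_times)) spike_times <- detect_spikes(V, fs = fs)
  if (!length(spike_times)) stop_invalid("no spikes to plot")
  d <- dvdt_trace(V, fs)
  nb <- round(window_ms[1] * fs / 1000)
  na_ <- round(window_ms[2] * fs / 1000)
  curves <- list()
  skipped <- 0L
  for (ts in spike_times) {
    i0 <- round(ts * fs) + 1L
    # anchor at the local voltage peak after the detection point
    seg_end <- min(length(V), i0 + na_)
    ipk <- i0 + which.max(V[i0:seg_end]) - 1L
    lo <- ipk - nb; hi <- ipk + na_
    if (lo < 1 || hi > length(V)) { skipped <- skipped + 1L; next }
    idx <- lo:hi
    curves[[length(curves) + 1L]] <-
      data.frame(t_ms = (idx - ipk) * 1000 / fs, V = V[idx], dvdt = d[idx])
  }
  if (skipped) warning(sprintf("%d spike(s) with truncated windows skipped", skipped))
  if (!length(curves)) stop_invalid("all spike windows truncated")
  avg <- NULL
  Vm <- vapply(curves, `[[`, numeric(nrow(curves[[1]])), "V")
  Dm <- vapply(curves, `[[`, numeric(nrow(curves[[1]])), "dvdt")
  if (length(curves) == 1) { Vm <- cbind(Vm); Dm <- cbind(Dm) }
  sem <- function(m) if (ncol(m) > 1) apply(m, 1, stats::sd) / sqrt(ncol(m)) else 0 * m[, 1]
  avg <- data.frame(t_ms = curves[[1]]$t_ms,
                    V = rowMeans(Vm), V_sem = sem(Vm),
                    dvdt = rowMeans(Dm), dvdt_sem = sem(Dm))
  structure(list(spikes = curves, average = avg, fs = fs), class = "phase_plot")
}

#' Detect a rising-limb indentation in a phase plot
#'
#' The rising limb (from threshold to the point of maximal dV/dt) is
#' scanned for a local maximum followed by a local minimum; the spike is
#' classified as indented when the drop (prominence) reaches
#' `prominence_frac` of the maximal depolarization rate.
#'
#' @param dvdt dV/dt samples of the rising limb (threshold to peak
#'   dV/dt), mV/ms.
#' @param max_depol_rate maximal depolarization rate; defaults to
#'   `max(dvdt)`.
#' @param prominence_frac detection floor as a fraction of
#'   `max_depol_rate`.
#' @return list with `indented` (logical) and `prominence` (mV/ms).
#' @export
detect_indentation <- function(dvdt, max_depol_rate = max(dvdt),
                               prominence_frac = 0.1) {
  n <- length(dvdt)
  if (n < 10) stop_invalid("rising limb needs at least 10 samples")
  i_max <- which.max(dvdt)
  seg <- dvdt[seq_len(i_max)]
  ds <- diff(seg)
  prom <- 0
  if (length(ds) > 2) {
    sgn <- sign(ds)
    sgn[sgn == 0] <- 1
    turns <- which(diff(sgn) != 0) + 1L
    maxima <- turns[sgn[turns - 1L] > 0]
    minima <- turns[sgn[turns - 1L] < 0]
    for (mx in maxima) {
      mn <- minima[minima > mx]
      if (length(mn)) prom <- max(prom, seg[mx] - min(seg[mn]))
    }
  }
  list(indented = prom >= prominence_frac * max_depol_rate, prominence = prom)
}

#' Extract AP features from a single-spike voltage trace
#'
#' Measures the feature battery on one spike: threshold (the
#' rising-limb voltage where dV/dt first reaches `threshold_frac` of its
#' maximum), amplitude from threshold, duration at half amplitude,
#' maximal depolarization and repolarization rates, mAHP amplitude
#' (threshold to the post-spike minimum within `ahp_window_ms`) and mAHP
#' half-width, and the indentation classification.
#'
#' @param V voltage trace containing one spike (mV), e.g. an
#'   `ap_waveform$V` or a window cut from a sweep.
#' @param fs sampling rate, Hz.
#' @param threshold_frac fraction of the maximal dV/dt defining the
#'   threshold point.
#' @param ahp_window_ms post-peak search window for the mAHP trough, ms.
#' @return object of class `ap_feature_set` with fields `threshold_V`,
#'   `amplitude_from_threshold`, `half_width`, `max_depol_rate`,
#'   `max_repol_rate` (signed, negative), `mahp_amplitude`,
#'   `mahp_half_width`, `indented`, `indent_prominence`. mAHP fields are
#'   `NA` (with a warning) when the trace ends before the trough or
#'   recovery.
#' @export
ap_features <- function(V, fs, threshold_frac = 0.04, ahp_window_ms = 500) {
  if (inherits(V, "ap_waveform")) { fs <- V$fs; V <- V$V }
  V <- as.numeric(V)
  d <- dvdt_trace(V, fs)
  i_peak <- which.max(V)
  if (i_peak < 3 || i_peak > length(V) - 2)
    stop_invalid("no interior voltage peak found")
  rise <- seq_len(i_peak)
  i_maxd <- which.max(d[rise])
  max_depol <- d[i_maxd]
  # threshold: last point before max dV/dt where dV/dt < frac * max
  below <- which(d[seq_len(i_maxd)] < threshold_frac * max_depol)
  i_thr <- if (length(below)) max(below) else 1L
  thr_V <- if (i_thr < i_maxd)
    cross_interp(V, d, i_thr, threshold_frac * max_depol) else V[i_thr]
  amp <- V[i_peak] - thr_V
  half <- thr_V + amp / 2
  # half-width between interpolated crossings around the peak
  upi <- max(which(V[seq_len(i_peak)] <= half))
  t_up <- cross_interp(seq_along(V) / fs, V, upi, half)
  after <- V[i_peak:length(V)]
  dn <- which(after <= half)
  if (!length(dn)) stop_invalid("trace ends before repolarization to half amplitude")
  dni <- i_peak + dn[1] - 2L
  t_dn <- cross_interp(seq_along(V) / fs, V, dni, half)
  half_width <- (t_dn - t_up) * 1000

  n_ahp <- min(length(V), i_peak + round(ahp_window_ms * fs / 1000))
  post <- V[i_peak:n_ahp]
  i_tr <- i_peak + which.min(post) - 1L
  max_repol <- min(d[i_peak:i_tr])
  mahp <- NA_real_; mahp_hw <- NA_real_
  if (i_tr == length(V)) {
    warning("trace ends before the mAHP trough; mAHP fields are NA")
  } else {
    mahp <- thr_V - V[i_tr]
    if (mahp > 0) {
      lev <- thr_V - mahp / 2
      pre <- which(V[i_peak:i_tr] <= lev)
      if (length(pre)) {
        i1 <- i_peak + pre[1] - 2L
        t1 <- cross_interp(seq_along(V) / fs, V, i1, lev)
        rec <- which(V[i_tr:length(V)] >= lev)
        if (length(rec)) {
          i2 <- i_tr + rec[1] - 2L
          t2 <- cross_interp(seq_along(V) / fs, V, i2, lev)
          mahp_hw <- (t2 - t1) * 1000
        } else {
          warning("trace ends before mAHP recovery; half-width is NA")
        }
      }
    }
  }
  ind <- detect_indentation(d[i_thr:rise[i_maxd]], max_depol_rate = max_depol)
  structure(list(threshold_V = thr_V, amplitude_from_threshold = amp,
                 half_width = half_width, max_depol_rate = max_depol,
                 max_repol_rate = max_repol, mahp_amplitude = mahp,
                 mahp_half_width = mahp_hw, indented = ind$indented,
                 indent_prominence = ind$prominence),
            class = "ap_feature_set")
}

#' @export
print.ap_feature_set <- function(x, ...) {
  cat(sprintf(paste0("<ap_feature_set> threshold %.1f mV, amplitude %.1f mV, ",
                     "half-width %.2f ms, dV/dt max %.1f / %.1f mV/ms, ",
                     "mAHP %.1f mV / %.0f ms, indented = %s\n"),
              x$threshold_V, x$amplitude_from_threshold, x$half_width,
              x$max_depol_rate, x$max_repol_rate, x$mahp_amplitude,
              x$mahp_half_width, x$indented))
  invisible(x)
}

#' Half-width of an afterhyperpolarization deflection
#'
#' Duration between the two half-amplitude crossings of a
#' hyperpolarizing deflection below a baseline (e.g. the mAHP after a
#' spike, taken relative to the threshold, or the AHP after a step).
#'
#' @param V voltage trace starting at/near the baseline and containing
#'   the AHP trough and recovery, mV.
#' @param fs sampling rate, Hz.
#' @param baseline reference voltage, mV; defaults to `V[1]`.
#' @param min_amplitude minimum deflection, mV.
#' @return half-width in ms, or `NA` with a warning when the recovery
#'   crossing is not reached.
#' @export
ahp_half_width <- function(V, fs, baseline = NULL, min_amplitude = 1) {
  V <- as.numeric(V)
  if (is.null(baseline)) baseline <- V[1]
  i_tr <- which.min(V)
  amp <- baseline - V[i_tr]
  if (amp < min_amplitude)
    stop_invalid("AHP amplitude %.2f mV below the %.1f mV minimum", amp, min_amplitude)
  lev <- baseline - amp / 2
  pre <- which(V[seq_len(i_tr)] <= lev)
  if (!length(pre)) stop_invalid("no descending half-amplitude crossing")
  i1 <- pre[1] - 1L
  t1 <- if (i1 >= 1) cross_interp(seq_along(V) / fs, V, i1, lev) else 1 / fs
  rec <- which(V[i_tr:length(V)] >= lev)
  if (!length(rec)) {
    warning("recovery crossing not reached; AHP half-width is NA")
    return(NA_real_)
  }
  i2 <- i_tr + rec[1] - 2L
  t2 <- cross_interp(seq_along(V) / fs, V, i2, lev)
  (t2 - t1) * 1000
}

#' Firing rate and ISI coefficient of variation
#'
#' Mean rate over an observation window and the coefficient of
#' variation of inter-spike intervals (SD/mean), the summary used for
#' 2-minute spontaneous recordings.
#'
#' @param x spike times in seconds, or a [sweep_recording()] (spikes
#'   detected or taken from the ground truth).
#' @param window observation window, seconds; defaults to 120 s or the
#'   sweep duration.
#' @return object of class `firing_stats`: `mean_rate` (Hz), `cv_isi`
#'   (`NA` with fewer than 3 spikes), `n_spikes`, `window`.
#' @export
firing_stats <- function(x, window = NULL) {
  if (inherits(x, "sweep_recording")) {
    st <- x$spike_times
    if (is.null(st)) st <- detect_spikes(x)
    if (is.null(window)) window <- max(x$t)
  } else {
    st <- as.numeric(x)
    if (is.null(window)) window <- 120
  }
  st <- st[st >= 0 & st <= window]
  n <- length(st)
  cv <- NA_real_
  if (n >= 3) {
    isi <- diff(st)
    cv <- stats::sd(isi) / mean(isi)
  }
  structure(list(mean_rate = n / window, cv_isi = cv, n_spikes = n,
                 window = window),
            class = "firing_stats")
}

#' @export
print.firing_stats <- function(x, ...) {
  cat(sprintf("<firing_stats> %.2f Hz over %.0f s (n = %d), CV(ISI) = %s\n",
              x$mean_rate, x$window, x$n_spikes,
              if (is.na(x$cv_isi)) "NA" else sprintf("%.2f", x$cv_isi)))
  invisible(x)
}

#' Intensity-frequency (I-F) curve
#'
#' Mean firing frequency (spike count during the step divided by the
#' step duration) across an amplitude series of 1-s depolarizing steps.
#'
#' @param ms a [membrane_scenario()] or list of [sweep_recording()]s.
#' @param amplitudes step amplitudes, pA (simulation input).
#' @param duration step duration, seconds.
#' @param fs sampling rate for simulation, Hz.
#' @return data.frame with columns `I` (pA) and `freq` (Hz).
#' @export
if_curve <- function(ms, amplitudes = seq(0, 120, by = 20), duration = 1,
                     fs = 10000) {
  sweeps <- if (inherits(ms, "membrane_scenario")) {
    lapply(amplitudes, function(a)
      simulate_current_step(ms, a, t_on = 0.1, t_off = 0.1 + duration, fs = fs))
  } else ms
  rows <- lapply(sweeps, function(sw) {
    st <- sw$spike_times
    if (is.null(st)) st <- detect_spikes(sw)
    n <- sum(st >= sw$step$t_on & st < sw$step$t_off)
    data.frame(I = sw$step$amplitude,
               freq = n / (sw$step$t_off - sw$step$t_on))
  })
  out <- do.call(rbind, rows)
  out[order(out$I), ]
}
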