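# Synthetic current-clamp electrophysiology: a leaky-integrator membrane
# with an HCN-like sag component and stereotyped action-potential
# waveforms spliced in at threshold crossings. The waveform synthesis is
# constructive: every shape parameter (threshold, amplitude, half-width,
# depolarization/repolarization rates, mAHP amplitude and half-width,
# rising-limb indentation) is met by design so that the feature
# extractors can be validated by round trip.

#' Action-potential shape parameters
#'
#' @param threshold spike threshold, mV.
#' @param amplitude_from_threshold peak height above threshold, mV.
#' @param half_width duration at half amplitude, ms. Must be at least the
#'   minimum achievable given the rates (see [min_half_width()]); the
#'   excess is realised as time spent near the peak.
#' @param max_depol_rate maximum rising dV/dt, mV/ms.
#' @param max_repol_rate maximum falling dV/dt, mV/ms (negative).
#' @param mahp_amplitude medium-AHP depth below threshold, mV.
#' @param mahp_half_width mAHP duration at half amplitude, ms.
#' @param indented logical; carve a local dV/dt minimum into the rising
#'   limb (initial-segment indentation).
#' @param notch_depth indentation prominence as a fraction of
#'   `max_depol_rate`; must be positive iff `indented`.
#' @return object of class `ap_shape`.
#' @export
ap_shape_params <- function(threshold = -41, amplitude_from_threshold = 56,
                            half_width = 5, max_depol_rate = 40,
                            max_repol_rate = -12, mahp_amplitude = 8,
                            mahp_half_width = 130, indented = FALSE,
                            notch_depth = 0) {
  check_positive(amplitude_from_threshold, "amplitude_from_threshold")
  check_positive(half_width, "half_width")
  check_positive(max_depol_rate, "max_depol_rate")
  if (max_repol_rate >= 0) stop_invalid("max_repol_rate must be negative")
  check_nonneg(mahp_amplitude, "mahp_amplitude")
  if (mahp_amplitude > 0) check_positive(mahp_half_width, "mahp_half_width")
  if (notch_depth < 0 || notch_depth >= 1)
    stop_invalid("notch_depth must be in [0, 1)")
  if (isTRUE(indented) != (notch_depth > 0))
    stop_invalid("notch_depth must be > 0 exactly when indented")
  if (indented && notch_depth > 0.6)
    stop_invalid("notch_depth above 0.6 is not representable")
  structure(list(threshold = threshold,
                 amplitude_from_threshold = amplitude_from_threshold,
                 half_width = half_width, max_depol_rate = max_depol_rate,
                 max_repol_rate = max_repol_rate,
                 mahp_amplitude = mahp_amplitude,
                 mahp_half_width = mahp_half_width,
                 indented = isTRUE(indented), notch_depth = notch_depth),
            class = "ap_shape")
}

# Half-cosine easing between (t0,y0) and (t1,y1).
cos_ease <- function(tau, t0, t1, y0, y1) {
  s <- (tau - t0) / (t1 - t0)
  y0 + (y1 - y0) * (1 - cos(pi * s)) / 2
}

# Rising-limb velocity profile on the unit interval, mV/ms. For indented
# shapes the profile passes a pre-peak local maximum v1 and a local
# minimum v1 - notch_depth * r_max before climbing to r_max, so the
# phase-plot prominence equals notch_depth * r_max by construction.
ap_rise_profile <- function(p, tau) {
  r <- p$max_depol_rate
  if (!p$indented) return(r * sin(pi * tau))
  d <- p$notch_depth * r
  v1 <- min(0.9, max(0.55, p$notch_depth + 0.2)) * r
  v2 <- v1 - d
  t1 <- 0.20; t2 <- 0.38; t3 <- 0.62
  v <- numeric(length(tau))
  i <- tau <= t1
  v[i] <- cos_ease(tau[i], 0, t1, 0, v1)
  i <- tau > t1 & tau <= t2
  v[i] <- cos_ease(tau[i], t1, t2, v1, v2)
  i <- tau > t2 & tau <= t3
  v[i] <- cos_ease(tau[i], t2, t3, v2, r)
  i <- tau > t3
  v[i] <- cos_ease(tau[i], t3, 1, r, 0)
  v
}

# Geometry of the synthesised waveform (all times ms): rise duration,
# half-amplitude up-crossing, fall duration, fall half-crossing, and the
# time spent between the mAHP half level and the trough on the fall.
ap_geometry <- function(p, n_grid = 4000) {
  tau <- seq(0, 1, length.out = n_grid + 1)
  v <- ap_rise_profile(p, tau)
  cum <- cumtrapz(tau, v)
  area <- cum[length(cum)]
  T_r <- p$amplitude_from_threshold / area
  # half-amplitude up-crossing: cumulative rise reaches amp/2
  tau_half <- stats::approx(cum / area, tau, xout = 0.5, ties = "ordered")$y
  t_up <- tau_half * T_r
  amp <- p$amplitude_from_threshold
  drop_total <- amp + p$mahp_amplitude
  f_max <- abs(p$max_repol_rate)
  T_f <- pi * drop_total / (2 * f_max)
  sigma_half <- acos(1 - 2 * (amp / 2) / drop_total) / pi
  t_f_half <- sigma_half * T_f
  # fall crossing of the mAHP half level (threshold - mahp/2)
  if (p$mahp_amplitude > 0) {
    sigma_ahp <- acos(1 - 2 * (amp + p$mahp_amplitude / 2) / drop_total) / pi
    t_fall_to_trough <- (1 - sigma_ahp) * T_f
  } else {
    t_fall_to_trough <- 0
  }
  list(tau = tau, v = v, cum = cum / area, T_r = T_r, t_up = t_up,
       T_f = T_f, t_f_half = t_f_half, t_fall_to_trough = t_fall_to_trough,
       hw_min = (T_r - t_up) + t_f_half)
}

#' Minimum achievable half-width for an AP shape
#'
#' The synthesised rise and fall alone imply a floor on the duration at
#' half amplitude; requested half-widths above the floor are realised by
#' dwell time at the peak.
#'
#' @param p an [ap_shape_params()] object.
#' @return minimum half-width, ms.
#' @export
min_half_width <- function(p) ap_geometry(p)$hw_min

#' Synthesise a single action-potential waveform
#'
#' Builds the voltage trace of one spike from its shape parameters:
#' a shaped rising limb whose maximum dV/dt equals `max_depol_rate`
#' (with an optional indentation), a raised-cosine repolarization to the
#' mAHP trough with peak rate `max_repol_rate`, and an exponential
#' recovery tuned so the mAHP half-width matches `mahp_half_width`.
#'
#' @param p an [ap_shape_params()] object.
#' @param fs sampling rate, Hz; must resolve the half-width with at
#'   least 10 samples.
#' @param include_recovery logical; append the mAHP recovery tail
#'   (needed to measure mAHP half-width). `FALSE` stops at the trough.
#' @return list of class `ap_waveform`: `V` (mV), `t` (s), `fs`,
#'   `i_peak`, `i_trough` sample indices, and `params`.
#' @export
make_ap_waveform <- function(p, fs = 50000, include_recovery = TRUE) {
  stopifnot(inherits(p, "ap_shape"))
  check_positive(fs, "fs")
  dt <- 1000 / fs  # ms per sample
  if (p$half_width / dt < 10)
    stop_invalid("sampling rate too low: half_width covers < 10 samples")
  g <- ap_geometry(p)
  if (p$half_width < g$hw_min - 1e-9)
    stop_invalid("half_width %.3f ms below the %.3f ms floor implied by the rates",
                 p$half_width, g$hw_min)
  T_p <- p$half_width - g$hw_min
  thr <- p$threshold
  amp <- p$amplitude_from_threshold

  t_rise <- seq(0, g$T_r, by = dt)
  V_rise <- thr + amp * stats::approx(g$tau, g$cum, xout = t_rise / g$T_r,
                                      ties = "ordered")$y
  n_plat <- floor(T_p / dt)
  V_plat <- rep(thr + amp, n_plat)
  t_fall <- seq(dt, g$T_f, by = dt)
  drop_total <- amp + p$mahp_amplitude
  V_fall <- thr + amp - drop_total * (1 - cos(pi * t_fall / g$T_f)) / 2

  V <- c(V_rise, V_plat, V_fall)
  i_trough <- length(V)
  if (include_recovery && p$mahp_amplitude > 0) {
    tau_rec <- (p$mahp_half_width - g$t_fall_to_trough) / log(2)
    if (tau_rec <= 0)
      stop_invalid("mahp_half_width too short for the repolarization rate")
    t_rec <- seq(dt, 7 * tau_rec, by = dt)
    V <- c(V, thr - p$mahp_amplitude * exp(-t_rec / tau_rec))
  }
  structure(list(V = V, t = (seq_along(V) - 1) / fs, fs = fs,
                 i_peak = length(t_rise) + max(1L, n_plat) - (n_plat == 0L),
                 i_trough = i_trough, params = p),
            class = "ap_waveform")
}

#' Draw random, self-consistent AP shape parameter sets
#'
#' Samples shape parameters over physiological ranges for cholinergic
#' interneurons (broad spikes, ~40 mV/ms rise, prominent mAHP), with the
#' half-width drawn above its achievable floor, for parameter-recovery
#' studies.
#'
#' @param n number of parameter sets.
#' @param seed integer seed.
#' @param p_indented probability of an indented (notched) rising limb.
#' @return list of [ap_shape_params()] objects.
#' @export
sample_ap_shapes <- function(n, seed = NULL, p_indented = 0.5) {
  with_seed(seed, lapply(seq_len(n), function(i) {
    indented <- stats::runif(1) < p_indented
    p <- ap_shape_params(
      threshold = stats::runif(1, -45, -38),
      amplitude_from_threshold = stats::runif(1, 45, 62),
      half_width = 20,  # placeholder above any floor; replaced below
      max_depol_rate = stats::runif(1, 25, 55),
      max_repol_rate = -stats::runif(1, 9, 16),
      mahp_amplitude = stats::runif(1, 4, 10),
      mahp_half_width = stats::runif(1, 100, 250),
      indented = indented,
      notch_depth = if (indented) stats::runif(1, 0.15, 0.45) else 0)
    p$half_width <- min_half_width(p) * stats::runif(1, 1.02, 1.35)
    p
  }))
}

#' Describe a synthetic membrane (leaky integrator with sag)
#'
#' @param R_m input resistance, MOhm.
#' @param tau_m membrane time constant, ms.
#' @param E_L resting potential, mV.
#' @param V_th spike threshold, mV; defaults to the AP shape threshold.
#' @param reset post-spike reset potential, mV; defaults to the mAHP
#'   trough (threshold - mahp_amplitude).
#' @param sag_fraction fraction of the steady-state deflection removed by
#'   the sag conductance during hyperpolarizing steps (0 = no sag,
#'   must be < 1).
#' @param sag_tau sag activation time constant, ms.
#' @param ap_shape an [ap_shape_params()] object for spliced spikes.
#' @param noise_sd measurement noise SD added to the voltage, mV.
#' @param seed integer seed for the noise.
#' @return object of class `membrane_scenario`.
#' @export
membrane_scenario <- function(R_m = 250, tau_m = 30, E_L = -60, V_th = NULL,
                              reset = NULL, sag_fraction = 0, sag_tau = 100,
                              ap_shape = ap_shape_params(), noise_sd = 0,
                              seed = NULL) {
  check_positive(R_m, "R_m")
  check_positive(tau_m, "tau_m")
  check_positive(sag_tau, "sag_tau")
  if (sag_fraction < 0 || sag_fraction >= 1)
    stop_invalid("sag_fraction must be in [0, 1)")
  check_nonneg(noise_sd, "noise_sd")
  if (is.null(V_th)) V_th <- ap_shape$threshold
  if (is.null(reset)) reset <- V_th - ap_shape$mahp_amplitude
  structure(list(R_m = R_m, tau_m = tau_m, E_L = E_L, V_th = V_th,
                 reset = reset, sag_fraction = sag_fraction, sag_tau = sag_tau,
                 ap_shape = ap_shape, noise_sd = noise_sd, seed = seed),
            class = "membrane_scenario")
}

#' Closed-form subthreshold step response
#'
#' Analytic deflection (mV, relative to rest) of the leaky integrator
#' with sag: the membrane filters a drive `R_m * I * (1 - s * z(t))`
#' where the sag gate `z` relaxes exponentially with `sag_tau` while the
#' step is on. Sag engages only for hyperpolarizing steps.
#'
#' @param ms a [membrane_scenario()].
#' @param amplitude step amplitude, pA.
#' @param t time since step onset, seconds (vector).
#' @return deflection in mV at each `t`.
#' @export
step_response <- function(ms, amplitude, t) {
  tm <- ms$tau_m / 1000
  ts <- ms$sag_tau / 1000
  D <- ms$R_m * amplitude / 1000  # mV
  base <- 1 - exp(-t / tm)
  s <- if (amplitude < 0) ms$sag_fraction else 0
  if (s == 0) return(D * base)
  # first-order filter (tau_m) applied to the sag gate 1 - exp(-t/ts)
  sagf <- 1 - (ts * exp(-t / ts) - tm * exp(-t / tm)) / (ts - tm)
  D * (base - s * sagf)
}

#' Find the sag fraction that produces a target sag ratio
#'
#' Inverts the closed-form step response: searches for the
#' `sag_fraction` whose analytic peak-to-end deflection ratio during a
#' 1-s step equals `target_ratio`.
#'
#' @param target_ratio desired peak/steady deflection ratio (>= 1).
#' @param ms membrane scenario providing `R_m`, `tau_m`, `sag_tau`.
#' @param amplitude step amplitude, pA (hyperpolarizing).
#' @param step_dur step duration, seconds.
#' @return sag fraction in [0, 1).
#' @export
sag_fraction_for_ratio <- function(target_ratio, ms = membrane_scenario(),
                                   amplitude = -100, step_dur = 1) {
  if (target_ratio < 1) stop_invalid("target_ratio must be >= 1")
  if (target_ratio == 1) return(0)
  ratio_of <- function(s) {
    m2 <- ms; m2$sag_fraction <- s
    tt <- seq(0, step_dur, by = 1e-4)
    d <- abs(step_response(m2, amplitude, tt))
    max(d) / d[length(d)]
  }
  stats::uniroot(function(s) ratio_of(s) - target_ratio,
                 interval = c(1e-6, 0.9), tol = 1e-9)$root
}

#' Simulate a current-clamp step sweep
#'
#' Integrates the leaky-integrator membrane with exact per-sample
#' exponential updates (drive held constant across each sample). When the
#' voltage crosses threshold, the stereotyped AP waveform (rise to mAHP
#' trough) is spliced in and integration resumes from the reset
#' potential. Gaussian measurement noise is added afterwards.
#'
#' @param ms a [membrane_scenario()].
#' @param amplitude step amplitude, pA.
#' @param t_on,t_off step onset/offset, seconds.
#' @param t_end sweep end, seconds.
#' @param fs sampling rate, Hz (>= 10 kHz recommended for waveform work).
#' @return a [sweep_recording()] carrying the step descriptor and the
#'   ground-truth spike times.
#' @export
simulate_current_step <- function(ms, amplitude, t_on = 0.1, t_off = 1.1,
                                  t_end = t_off + 0.4, fs = 10000) {
  stopifnot(inherits(ms, "membrane_scenario"))
  if (t_on >= t_off || t_off > t_end)
    stop_invalid("need t_on < t_off <= t_end")
  n <- round(t_end * fs)
  t <- (seq_len(n) - 1) / fs
  I <- ifelse(t >= t_on & t < t_off, amplitude, 0)
  dt_ms <- 1000 / fs
  a_m <- exp(-dt_ms / ms$tau_m)
  a_s <- exp(-dt_ms / ms$sag_tau)
  # splice waveforms anchored at the scenario threshold so the voltage
  # trace stays continuous even when V_th differs from the shape default
  wf_shape <- ms$ap_shape
  wf_shape$threshold <- ms$V_th
  wf <- make_ap_waveform(wf_shape, fs = fs, include_recovery = FALSE)
  nw <- length(wf$V)

  V <- numeric(n)
  V[1] <- ms$E_L
  z <- 0
  spikes <- numeric(0)
  k <- 1L
  while (k < n) {
    s_eff <- if (I[k] < 0) ms$sag_fraction else 0
    drive <- ms$R_m * I[k] / 1000 * (1 - s_eff * z)
    Vinf <- ms$E_L + drive
    V[k + 1L] <- Vinf + (V[k] - Vinf) * a_m
    z_target <- as.numeric(I[k] != 0)
    z <- z_target + (z - z_target) * a_s
    k <- k + 1L
    if (V[k] >= ms$V_th) {
      spikes <- c(spikes, t[k])
      idx <- k:min(n, k + nw - 1L)
      V[idx] <- wf$V[seq_along(idx)]
      k <- idx[length(idx)]
      if (k < n) V[k] <- ms$reset
    }
  }
  if (ms$noise_sd > 0)
    V <- V + with_seed(ms$seed, stats::rnorm(n, sd = ms$noise_sd))
  sweep_recording(t, V, I, fs = fs,
                  step = list(amplitude = amplitude, t_on = t_on, t_off = t_off),
                  spike_times = spikes)
}
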