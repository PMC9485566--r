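# Current-clamp feature battery.

test_that("spike detection finds inserted APs and ignores noise", {
  ms <- membrane_scenario(R_m = 300, tau_m = 30, E_L = -60, V_th = -45)
  sw <- simulate_current_step(ms, 100, fs = 20000)
  det <- detect_spikes(sw)
  expect_equal(length(det), length(sw$spike_times))
  expect_true(all(abs(det - sw$spike_times) < 0.001))
  # flat and noise-only traces: nothing detected
  expect_length(detect_spikes(rep(-60, 5000), fs = 10000), 0)
  set.seed(3)
  expect_length(detect_spikes(-60 + stats::rnorm(5000, sd = 0.3), fs = 10000), 0)
})

test_that("cubic I-V fit recovers linear and cubic resistances", {
  # linear membranes at the two observed regimes
  for (R in c(235.6, 363.2)) {
    amps <- seq(-100, 20, by = 20)
    sweeps <- lapply(amps, function(a)
      simulate_current_step(membrane_scenario(R_m = R, tau_m = 25, E_L = -60,
                                              V_th = 0), a, fs = 10000))
    iv <- fit_iv(sweeps, eval_at = -60)
    expect_equal(iv$R_N, R, tolerance = 0.001)
  }
  # cubic-generated points: derivative matches the generating polynomial
  b <- c(-62, 0.31, 4e-4, 6e-7)
  I <- seq(-120, 60, by = 20)
  iv2 <- fit_iv(data.frame(I = I, V = b[1] + b[2] * I + b[3] * I^2 + b[4] * I^3),
                eval_at = -60)
  dtrue <- function(I) (b[2] + 2 * b[3] * I + 3 * b[4] * I^2) * 1000
  expect_equal(iv2$R_N, dtrue(iv2$eval_I), tolerance = 0.005)
  expect_error(fit_iv(data.frame(I = 1:3, V = 1:3)), "at least 4")
})

test_that("rheobase matches the analytic LIF value within one grid step", {
  grid <- expand.grid(R = c(100, 200, 300, 400, 500), tau = c(10, 30, 50))
  for (i in seq_len(nrow(grid))) {
    R <- grid$R[i]; tau <- grid$tau[i]
    ms <- membrane_scenario(R_m = R, tau_m = tau, E_L = -60, V_th = -45)
    rb <- rheobase(ms, amplitudes = seq(5, 300, by = 5))
    analytic <- lif_rheobase(R, tau, 15)
    expect_lte(abs(rb$rheobase - analytic), 5 + 1e-9)
  }
  # doubling the threshold distance doubles rheobase (within one step)
  ms1 <- membrane_scenario(R_m = 300, tau_m = 30, E_L = -60, V_th = -45)
  ms2 <- membrane_scenario(R_m = 300, tau_m = 30, E_L = -60, V_th = -30)
  r1 <- rheobase(ms1, amplitudes = seq(5, 300, 5))$rheobase
  r2 <- rheobase(ms2, amplitudes = seq(5, 300, 5))$rheobase
  expect_lte(abs(r2 - 2 * r1), 10)
  # all-subthreshold grid errors out
  expect_error(rheobase(ms1, amplitudes = c(5, 10)), "no spiking")
})

test_that("sag ratio: exactly 1 without sag, recovers tuned regimes", {
  ms <- membrane_scenario(R_m = 300, tau_m = 25, E_L = -60, V_th = 0)
  sw <- simulate_current_step(ms, -100, fs = 10000)
  expect_equal(sag_ratio(sw), 1, tolerance = 0.002)
  for (target in c(1.019, 1.053)) {
    s <- sag_fraction_for_ratio(target, ms)
    ms2 <- membrane_scenario(R_m = 300, tau_m = 25, E_L = -60, V_th = 0,
                             sag_fraction = s)
    sw2 <- simulate_current_step(ms2, -100, fs = 10000)
    expect_equal(sag_ratio(sw2), target, tolerance = 0.001)
  }
  expect_error(sag_ratio(simulate_current_step(ms, 20)), "hyperpolarizing")
})

test_that("phase plots honour calculus and shift/offset invariance", {
  # sinusoid: max dV/dt = 2*pi*f*amplitude
  fs <- 20000; f <- 5
  tt <- seq(0, 1, by = 1 / fs)
  V <- 10 * sin(2 * pi * f * tt)
  d <- cinscope:::dvdt_trace(V, fs)
  expect_equal(max(d), 2 * pi * f * 10 / 1000, tolerance = 0.001)
  # max dV/dt of a spike is invariant to time shift and voltage offset
  p <- ap_shape_params()
  wf <- make_ap_waveform(p)
  base <- ap_features(wf)
  shifted <- c(rep(wf$V[1], 500), wf$V) + 7.5
  f2 <- ap_features(shifted, fs = wf$fs)
  expect_equal(f2$max_depol_rate, base$max_depol_rate, tolerance = 1e-9)
  expect_equal(f2$amplitude_from_threshold, base$amplitude_from_threshold,
               tolerance = 0.01)
  # identical spikes average to themselves with zero SEM
  ms <- membrane_scenario(R_m = 300, tau_m = 30, E_L = -60, V_th = -45)
  sw <- simulate_current_step(ms, 100, fs = 50000)
  pp <- phase_plot(sw)
  expect_gt(length(pp$spikes), 1)
  expect_equal(max(pp$average$dvdt), p$max_depol_rate, tolerance = 0.02)
})

test_that("AP features round-trip the synthesis parameters within 5%", {
  shapes <- sample_ap_shapes(50, seed = 4242)
  for (p in shapes) {
    f <- ap_features(make_ap_waveform(p))
    expect_equal(f$threshold_V, p$threshold, tolerance = 0.05 * abs(p$threshold))
    expect_equal(f$amplitude_from_threshold, p$amplitude_from_threshold,
                 tolerance = 0.05 * p$amplitude_from_threshold)
    expect_equal(f$half_width, p$half_width, tolerance = 0.05 * p$half_width)
    expect_equal(f$max_depol_rate, p$max_depol_rate,
                 tolerance = 0.05 * p$max_depol_rate)
    expect_equal(f$max_repol_rate, p$max_repol_rate,
                 tolerance = 0.05 * abs(p$max_repol_rate))
    expect_equal(f$mahp_amplitude, p$mahp_amplitude,
                 tolerance = 0.05 * p$mahp_amplitude)
    expect_equal(f$mahp_half_width, p$mahp_half_width,
                 tolerance = 0.05 * p$mahp_half_width)
    expect_identical(f$indented, p$indented)
  }
})

test_that("indentation classification respects the prominence floor", {
  deep <- ap_shape_params(half_width = 7, indented = TRUE, notch_depth = 0.3)
  f1 <- ap_features(make_ap_waveform(deep))
  expect_true(f1$indented)
  expect_equal(f1$indent_prominence, 0.3 * deep$max_depol_rate,
               tolerance = 0.05 * 0.3 * deep$max_depol_rate)
  shallow <- ap_shape_params(half_width = 7, indented = TRUE,
                             notch_depth = 0.05)
  expect_false(ap_features(make_ap_waveform(shallow))$indented)
  smooth <- ap_shape_params()
  expect_false(ap_features(make_ap_waveform(smooth))$indented)
})

test_that("AHP half-width: triangular oracle and synthesized regimes", {
  # triangular AHP 10 mV deep over a 200 ms base: half-width 100 ms
  fs <- 10000
  half <- seq(0, -10, length.out = fs / 10)
  V <- -55 + c(half, rev(half))
  expect_equal(ahp_half_width(V, fs), 100, tolerance = 0.5)
  for (mhw in c(130.3, 216.9)) {
    p <- ap_shape_params(mahp_half_width = mhw)
    f <- ap_features(make_ap_waveform(p))
    expect_equal(f$mahp_half_width, mhw, tolerance = 0.05 * mhw)
  }
  # recovery never reached: NA with a warning
  Vtrunc <- -55 + seq(0, -10, length.out = 1000)
  expect_warning(out <- ahp_half_width(Vtrunc, fs), "recovery")
  expect_true(is.na(out))
})

test_that("firing statistics: periodic, gamma-renewal, and empty trains", {
  per <- firing_stats(seq(0.5, 120, by = 0.5), window = 120)
  expect_equal(per$mean_rate, 2)
  expect_equal(per$cv_isi, 0)
  st <- make_spike_train("irregular", rate = 4, cv = 0.5, duration = 600,
                         seed = 12)
  stats <- firing_stats(st$spike_times, window = 600)
  expect_gt(stats$n_spikes, 2000)
  expect_equal(stats$cv_isi, 0.5, tolerance = 0.05)
  empty <- firing_stats(numeric(0), window = 120)
  expect_equal(empty$mean_rate, 0)
  expect_true(is.na(empty$cv_isi))
})

test_that("I-F curves are zero below rheobase and non-decreasing", {
  ms <- membrane_scenario(R_m = 300, tau_m = 30, E_L = -60, V_th = -45)
  ifc <- if_curve(ms, amplitudes = seq(0, 120, by = 20))
  expect_true(all(ifc$freq[ifc$I <= 40] == 0))  # rheobase ~55 pA
  expect_true(all(diff(ifc$freq) >= 0))
})
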