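# Synthetic generators: spike trains, fluorescence forward model,
# movies, membrane simulation, AP waveform synthesis.

test_that("zero-CV renewal train is periodic with the requested rate", {
  st <- make_spike_train("tonic", rate = 2, cv = 0, duration = 10, seed = 99)
  expect_length(st$spike_times, 20)
  expect_equal(diff(st$spike_times), rep(0.5, 19), tolerance = 1e-12)
})

test_that("gamma-renewal trains recover the requested ISI CV", {
  for (cv in c(1, 0.5)) {
    st <- make_spike_train("irregular", rate = 4, cv = cv, duration = 600,
                           seed = 7)
    isi <- diff(st$spike_times)
    expect_equal(stats::sd(isi) / mean(isi), cv, tolerance = 0.05)
  }
})

test_that("spike trains satisfy their invariants and recover the rate", {
  for (seed in 1:5) {
    for (pat in c("tonic", "irregular", "burst_pause")) {
      st <- make_spike_train(pat, rate = 3, duration = 100, seed = seed)
      expect_true(all(diff(st$spike_times) > 0))
      expect_true(all(st$spike_times >= 0 & st$spike_times <= 100 + 1e-9))
      if (pat != "burst_pause") {
        n <- length(st$spike_times)
        # renewal-count SE ~ cv * sqrt(n); tonic cv 0.05, irregular cv 1
        se <- max(1, st$params$cv * sqrt(300))
        expect_lt(abs(n - 300), 3 * se + 3)
      }
    }
  }
})

test_that("spike train generation is seed-deterministic and validates input", {
  a <- make_spike_train("irregular", rate = 2, duration = 50, seed = 5)
  b <- make_spike_train("irregular", rate = 2, duration = 50, seed = 5)
  expect_identical(a$spike_times, b$spike_times)
  expect_error(make_spike_train("tonic", rate = -1, duration = 10),
               "positive")
  expect_error(make_spike_train("tonic", rate = 1, duration = 0), "positive")
})

test_that("noiseless rendering is kernels on baseline with matching truth", {
  # no spikes: constant at baseline
  sc <- imaging_scenario(2, duration = 10, fps = 10,
                         trains = lapply(1:2, function(i)
                           structure(list(spike_times = numeric(0),
                                          duration = 10, pattern = "tonic",
                                          params = list()),
                                     class = "spike_train")),
                         baseline_F0 = c(80, 120), seed = 1)
  rf <- render_fluorescence(sc)
  expect_equal(rf$traces$F, matrix(c(80, 120), 2, 100), tolerance = 1e-12)
  expect_equal(sum(rf$truth$A), 0)

  # one spike at t = 5 s: max within rise_tau of its frame, one raster 1
  tr <- structure(list(spike_times = 5, duration = 20, pattern = "tonic",
                       params = list()), class = "spike_train")
  sc1 <- imaging_scenario(1, duration = 20, fps = 10, trains = list(tr),
                          seed = 1)
  rf1 <- render_fluorescence(sc1)
  expect_equal(sum(rf1$truth$A), 1)
  expect_equal(which(rf1$truth$A[1, ] == 1), 51)
  t_max <- (which.max(rf1$traces$F[1, ]) - 1) / 10
  expect_lt(abs(t_max - 5), 0.05 + 0.11)  # rise_tau + one frame
})

test_that("Poisson ground-truth event counts match count statistics", {
  sc <- imaging_scenario(10, duration = 100, fps = 10,
                         trains = list(pattern = "irregular", rate = 3, cv = 1),
                         seed = 42)
  rf <- render_fluorescence(sc)
  # spike counts follow Poisson statistics
  n_spk <- lengths(rf$spike_times)
  expect_true(all(abs(n_spk - 300) < 4 * sqrt(300)))
  # raster counts: frames with >= 1 spike, i.e. C * (1 - exp(-rate/fps))
  counts <- rowSums(rf$truth$A)
  p_hit <- 1 - exp(-3 / 10)
  expect_true(all(abs(counts - 1000 * p_hit) <
                    4 * sqrt(1000 * p_hit * (1 - p_hit))))
})

test_that("rendering is deterministic in the scenario seed", {
  sc <- imaging_scenario(4, duration = 30, fps = 10,
                         trains = list(pattern = "irregular", rate = 2),
                         noise_sd = 0.02, seed = 8)
  expect_identical(render_fluorescence(sc)$traces$F,
                   render_fluorescence(sc)$traces$F)
})

test_that("ensemble events force coincident ground-truth frames", {
  ens <- list(list(time = 10, members = 1:5), list(time = 20, members = c(2, 4)))
  sc <- imaging_scenario(5, duration = 30, fps = 10,
                         trains = list(pattern = "irregular", rate = 0.5),
                         ensemble_events = ens, seed = 3)
  rf <- render_fluorescence(sc)
  expect_true(all(rf$truth$A[1:5, 101] == 1))
  expect_true(all(rf$truth$A[c(2, 4), 201] == 1))
  expect_error(imaging_scenario(3, duration = 10,
                                ensemble_events = list(list(time = 1, members = 9))),
               "valid cell indices")
})

test_that("rendered movies reproduce traces inside ROI disks", {
  sc <- imaging_scenario(3, duration = 8, fps = 10,
                         trains = list(pattern = "irregular", rate = 2),
                         noise_sd = 0.01, seed = 6)
  path <- withr::local_tempfile(fileext = ".tif")
  mv <- render_movie(sc, roi_radius = 3, field = c(32, 32), path = path)
  ext <- extract_roi_traces(path, mv$rois, fps = 10)
  for (i in 1:3)
    expect_gt(stats::cor(ext$F[i, ], mv$traces$F[i, ]), 0.99)
  # constant trace: identical pixels inside the disk across frames
  sc0 <- imaging_scenario(1, duration = 5, fps = 10,
                          trains = list(pattern = "irregular", rate = 1e-6),
                          seed = 2)
  mv0 <- render_movie(sc0, roi_radius = 3, field = c(16, 16))
  expect_identical(mv0$frames[[1]], mv0$frames[[5]])
  # over-large ROI cannot fit
  sc_empty <- imaging_scenario(1, duration = 2, fps = 10,
                               trains = list(pattern = "irregular", rate = 1),
                               seed = 1)
  expect_error(render_movie(sc_empty, roi_radius = 10, field = c(12, 12)),
               "fit inside")
})

test_that("membrane simulation matches the closed-form step response", {
  ms <- membrane_scenario(R_m = 300, tau_m = 30, E_L = -60, V_th = -41)
  for (s in c(0, 0.1, 0.25)) {
    ms$sag_fraction <- s
    sw <- simulate_current_step(ms, -100, fs = 10000)
    sel <- sw$t >= 0.1 & sw$t < 1.1
    pred <- ms$E_L + step_response(ms, -100, sw$t[sel] - 0.1)
    expect_lt(max(abs(sw$V[sel] - pred)), 0.1)
  }
  # steady-state deflection = R*I for sag-free, noiseless
  ms$sag_fraction <- 0
  sw <- simulate_current_step(ms, -100, fs = 10000)
  late <- sw$V[sw$t >= 1.0 & sw$t < 1.1]
  expect_equal(mean(late), -60 - 300 * 100 / 1000, tolerance = 1e-3)
})

test_that("AP waveform synthesis honours its shape parameters", {
  p <- ap_shape_params(max_depol_rate = 40)
  wf <- make_ap_waveform(p)
  d <- diff(wf$V) * wf$fs / 1000
  expect_equal(max(d), 40, tolerance = 0.02)
  expect_equal(max(wf$V), p$threshold + p$amplitude_from_threshold,
               tolerance = 1e-6)
  # no mAHP: no undershoot below threshold
  p0 <- ap_shape_params(mahp_amplitude = 0, mahp_half_width = 1)
  wf0 <- make_ap_waveform(p0)
  expect_gte(min(wf0$V), p0$threshold - 1e-9)
  # unresolvable half-width errors out
  expect_error(make_ap_waveform(p, fs = 1000), "sampling rate too low")
  expect_error(make_ap_waveform(ap_shape_params(half_width = 1)), "floor")
})

test_that("shape parameter validation enforces the indentation contract", {
  expect_error(ap_shape_params(indented = TRUE, notch_depth = 0),
               "notch_depth")
  expect_error(ap_shape_params(indented = FALSE, notch_depth = 0.2),
               "notch_depth")
  expect_error(ap_shape_params(max_repol_rate = 5), "negative")
})
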