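# dF/F0, derivative thresholding, rasters, viability.

test_that("dF/F0 follows its definition and scaling invariance", {
  ts <- fluor_traces(matrix(110, 1, 40), fps = 10, background = 100)
  d <- compute_dff(ts)
  expect_equal(d$dff[1, 1], 0.1)
  # constant trace: constant dff, zero derivative
  expect_equal(stats::sd(d$dff[1, ]), 0)
  expect_equal(max(abs(d$derivative)), 0)
  # linear ramp F = F0 (1 + a t): derivative constant = a
  a <- 0.02
  tt <- (0:99) / 10
  ts2 <- fluor_traces(matrix(100 * (1 + a * tt), 1, 100), fps = 10,
                      background = 100)
  d2 <- compute_dff(ts2)
  expect_equal(unique(round(d2$derivative[1, 1:99], 10)), a)
  # uniform rescaling of F and F0 leaves dff unchanged
  ts3 <- fluor_traces(7.3 * ts2$F, fps = 10, background = 7.3 * 100)
  expect_equal(compute_dff(ts3)$dff, d2$dff, tolerance = 1e-12)
  # non-positive F0 is an error naming the cell
  ts4 <- fluor_traces(matrix(1, 2, 40), fps = 10, background = c(1, 0))
  expect_error(compute_dff(ts4), "cell2")
})

test_that("rolling-percentile F0 tracks a quiescent baseline", {
  sc <- clean_scenario(n_cells = 3, rate = 0.3, duration = 120, seed = 4)
  rf <- render_fluorescence(sc)
  d <- compute_dff(rf$traces, f0_mode = "rolling")
  expect_true(all(abs(d$f0 - 100) / 100 < 0.1))
})

test_that("noiseless forward/inverse recovery is exact (Jaccard 1)", {
  for (seed in 1:3) {
    sc <- clean_scenario(seed = seed)
    rf <- render_fluorescence(sc)
    r <- infer_events(compute_dff(rf$traces))
    expect_equal(jaccard(r$A, rf$truth$A), 1)
  }
})

test_that("false-event rate on pure-noise derivatives matches the normal tail", {
  set.seed(2024)
  dv <- matrix(stats::rnorm(100 * 1000), 100, 1000)
  d <- dff_traces(matrix(0, 100, 1000), fps = 10, derivative = dv)
  r <- infer_events(d, collapse = FALSE)
  p <- stats::pnorm(2.5, lower.tail = FALSE)
  se <- sqrt(p * (1 - p) / (100 * 1000))
  expect_lt(abs(mean(r$A) - p), 3 * se)
})

test_that("raster is monotone in the threshold and flat traces stay silent", {
  sc <- clean_scenario(n_cells = 5, noise_sd = 0.02, seed = 11)
  d <- compute_dff(render_fluorescence(sc)$traces)
  r1 <- infer_events(d, k_sd = 2, collapse = FALSE)
  r2 <- infer_events(d, k_sd = 3, collapse = FALSE)
  expect_true(all(r2$A <= r1$A))
  # flat noiseless trace: zero-variance warning, all-zero raster
  dz <- dff_traces(matrix(0, 1, 50), fps = 10)
  expect_warning(rz <- infer_events(dz), "zero-variance")
  expect_equal(sum(rz$A), 0)
})

test_that("event recovery stays precise at moderate noise", {
  for (noise in c(0, 0.01, 0.02)) {
    sc <- clean_scenario(n_cells = 10, rate = 3, duration = 100,
                         noise_sd = noise, seed = 21)
    rf <- render_fluorescence(sc)
    r <- infer_events(compute_dff(rf$traces))
    tp <- sum(r$A & rf$truth$A)
    expect_gte(tp / sum(rf$truth$A), 0.95)  # recall
    expect_gte(tp / sum(r$A), 0.95)         # precision
  }
})

test_that("percent active is the active-frame percentage", {
  A <- rbind(rep(0, 200), rep(1, 200), c(rep(1, 5), rep(0, 195)))
  pa <- percent_active(event_raster(A, fps = 10))
  expect_equal(unname(pa), c(0, 100, 2.5))
})

test_that("viability filter applies the responsive-fraction rule", {
  A <- matrix(0L, 10, 100)
  A[1:8, 95] <- 1L   # 8 of 10 respond in the KCl segment
  v <- viability_filter(event_raster(A, fps = 10), kcl_segment = c(91, 100))
  expect_equal(v$fraction, 0.8)
  expect_false(v$keep)
  A[9:10, 96] <- 1L
  v2 <- viability_filter(event_raster(A, fps = 10), kcl_segment = c(91, 100))
  expect_equal(v2$fraction, 1)
  expect_true(v2$keep)
  expect_error(viability_filter(event_raster(A, fps = 10),
                                kcl_segment = c(101, 110)), "frame range")
})

test_that("ROI extraction handles uniform movies and edge cases", {
  frames <- replicate(5, matrix(100, 20, 20), simplify = FALSE)
  rois <- data.frame(id = "c1", x = 10, y = 10, radius = 3)
  ts <- extract_roi_traces(frames, rois, fps = 10)
  expect_equal(unique(as.numeric(ts$F)), 100)
  expect_equal(unique(as.numeric(ts$background)), 100)
  expect_error(extract_roi_traces(frames,
                                  data.frame(id = "c1", x = 2, y = 10, radius = 3)),
               "outside")
})
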