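# Coactivity, Monte-Carlo null, accumulation slopes, intervals, CDFs,
# rank tests.

test_that("coactivity counts are column sums and conserve events", {
  A <- matrix(0L, 3, 10)
  A[, 5] <- 1L
  r <- event_raster(A, fps = 10)
  cc <- coactivity(r)
  expect_equal(cc[5], 3L)
  expect_equal(sum(cc), sum(A))
  expect_equal(coactivity(event_raster(matrix(0L, 3, 10), fps = 10)),
               rep(0L, 10))
})

test_that("surrogate coincidence distribution matches exhaustive enumeration", {
  # 2 cells x 4 frames, one event each: all 16 circular-shift pairs give
  # coincidence probability 1/4, so pooled P(count = 2) = 1/16 and no
  # frame can be significant at alpha = 0.05 (threshold passes to 3).
  A <- matrix(0L, 2, 4); A[1, 2] <- 1L; A[2, 3] <- 1L
  pr <- mc_threshold(event_raster(A, fps = 10), n_surrogates = 10000,
                     seed = 77)
  exact <- c(`0` = 9 / 16, `1` = 6 / 16, `2` = 1 / 16)
  mc_se <- sqrt(exact * (1 - exact) / (4 * 10000))
  for (k in names(exact))
    expect_lt(abs(pr$surrogate_dist[k] - exact[k]), 4 * mc_se[k])
  expect_equal(pr$threshold, 3L)
  expect_equal(sum(pr$significant_frames), 0L)
})

test_that("type-I flagging stays at or below the nominal level", {
  rates <- vapply(1:3, function(seed) {
    sc <- imaging_scenario(20, duration = 600, fps = 10,
                           trains = list(pattern = "irregular", rate = 2),
                           seed = seed)
    rf <- render_fluorescence(sc)
    pr <- mc_threshold(rf$truth, n_surrogates = 1000, seed = seed + 50)
    mean(pr$significant_frames)
  }, numeric(1))
  expect_lt(mean(rates), 0.07)
})

test_that("embedded ensembles are detected above the surrogate threshold", {
  ens <- lapply(seq(20, 590, by = 30), function(tt)
    list(time = tt, members = 1:10))
  sc <- imaging_scenario(20, duration = 600, fps = 10,
                         trains = list(pattern = "irregular", rate = 2),
                         ensemble_events = ens, seed = 13)
  rf <- render_fluorescence(sc)
  pr <- mc_threshold(rf$truth, n_surrogates = 1000, seed = 14)
  emb <- floor(seq(20, 590, by = 30) * 10) + 1
  expect_gte(sum(pr$significant_frames[emb]), 18)
})

test_that("threshold seed-determinism and empty-raster handling", {
  A <- matrix(rbinom(200, 1, 0.2), 5, 40)
  r <- event_raster(A, fps = 10)
  p1 <- mc_threshold(r, n_surrogates = 200, seed = 3)
  p2 <- mc_threshold(r, n_surrogates = 200, seed = 3)
  expect_identical(p1$surrogate_dist, p2$surrogate_dist)
  expect_warning(pe <- mc_threshold(event_raster(matrix(0L, 3, 40), fps = 10),
                                    n_surrogates = 50, seed = 1),
                 "no events")
  expect_true(is.na(pe$threshold))
})

test_that("accumulation slope: exact for constant counts, linear in rate", {
  fit <- accumulation_slope(rep(3, 200), fps = 10)
  expect_equal(fit$slope, 3, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$slope_per_s, 30, tolerance = 1e-9)
  # chord of the cumulative equals (total - first)/(C - 1)
  counts <- rpois(500, 2)
  f2 <- accumulation_slope(counts)
  cum <- f2$cumulative
  expect_equal((cum[500] - cum[1]) / 499, (sum(counts) - counts[1]) / 499)
  # all-zero counts: zero slope
  expect_equal(accumulation_slope(rep(0, 50))$slope, 0)
  # doubling Poisson rates doubles the expected slope
  set.seed(31)
  s1 <- replicate(20, accumulation_slope(rpois(600, 2))$slope)
  s2 <- replicate(20, accumulation_slope(rpois(600, 4))$slope)
  se <- sqrt(stats::var(s2) / 20 + 4 * stats::var(s1) / 20)
  expect_lt(abs(mean(s2) - 2 * mean(s1)), 3 * se)
})

test_that("inter-event intervals and histograms follow their definitions", {
  A <- matrix(0L, 2, 120)
  A[1, c(1, 6, 11)] <- 1L   # events at frames 0, 5, 10 -> 0.5 s gaps
  A[2, 7] <- 1L             # single event contributes nothing
  iv <- iisi_extract(event_raster(A, fps = 10))
  expect_equal(iv$per_cell[[1]], c(0.5, 0.5))
  expect_length(iv$per_cell[[2]], 0)
  expect_equal(length(iv$pooled), sum(pmax(rowSums(A) - 1, 0)))

  hh <- iisi_histograms(c(0.2, 0.4, 30, 100))
  expect_equal(unname(hh$totals), c(2, 1, 1))
  expect_equal(hh$n_overflow, 0)
  hs <- iisi_histograms(c(0.1, 0.5, 0.9))
  expect_equal(unname(hs$totals), c(3, 0, 0))
  expect_equal(hh$cdf(1), 0.5)
})

test_that("burst/pause trains carry heavier long-interval mass than tonic", {
  mk <- function(pattern, seed, ...) {
    trains <- lapply(1:25, function(i)
      make_spike_train(pattern, rate = 2, duration = 300,
                       seed = seed + i, ...))
    unlist(lapply(trains, function(s) diff(s$spike_times)))
  }
  tonic <- mk("tonic", 100)
  bp <- mk("burst_pause", 200, burst_len = 2, pause_len = 2)
  kt <- suppressWarnings(stats::ks.test(tonic, bp))
  expect_lt(kt$p.value, 0.01)
  expect_gt(mean(bp > 1.5), mean(tonic > 1.5))
})

test_that("activity CDF comparisons: identical, shifted, Bonferroni", {
  x <- stats::rnorm(100, 10, 2)
  same <- activity_cdf(list(a = x, b = x), alpha = 0.05)
  expect_equal(same$comparisons[[1]]$ks_D, 0)
  expect_gt(same$comparisons[[1]]$p_value, 0.99)
  set.seed(5)
  shift <- activity_cdf(list(a = stats::rnorm(100), b = stats::rnorm(100) + 1))
  expect_lt(shift$comparisons[[1]]$p_value, 0.001)
  four <- activity_cdf(list(a = x, b = x + 1, c = x, d = x), alpha = 0.05,
                       comparisons = list(c("a", "b"), c("a", "c"),
                                          c("a", "d"), c("b", "c")))
  expect_equal(four$bonferroni_alpha, 0.0125)
  expect_error(activity_cdf(list(a = 1, b = x)), "fewer than 2")
})

test_that("group_compare dispatches the matching rank test", {
  x <- c(1.2, 3.1, 2.2, 5.5, 4.1, 2.0, 3.3, 1.1, 0.5, 2.8)
  ident <- group_compare(list(a = x, b = x), design = "paired")
  expect_equal(ident$p_value, 1)
  expect_match(ident$method, "Wilcoxon")
  set.seed(9)
  g1 <- stats::rgamma(30, 3, 1); g2 <- stats::rgamma(30, 3, 1) * 2
  mw <- group_compare(list(a = g1, b = g2), design = "unpaired")
  expect_match(mw$method, "Mann-Whitney")
  expect_lt(mw$p_value, 0.01)
  kw <- group_compare(list(a = x, b = x, c = x), design = "k_unpaired")
  expect_gt(kw$p_value, 0.99)
  expect_false(any(kw$posthoc$significant))
  fr <- group_compare(list(a = x, b = x + 3, c = x + 6), design = "k_paired")
  expect_lt(fr$p_value, 0.01)
  expect_error(group_compare(list(a = 1:5, b = 1:4), design = "paired"),
               "equal group lengths")
})

test_that("proportion comparison is the df = 1 chi-square", {
  eq <- proportion_compare(50, 100, 50, 100)
  expect_equal(eq$chi_sq, 0)
  expect_equal(eq$p_value, 1)
  diff <- proportion_compare(90, 100, 10, 100)
  expect_equal(diff$df, 1L)
  expect_lt(diff$p_value, 1e-4)
  expect_error(proportion_compare(5, 3, 1, 10), "exceed")
})
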