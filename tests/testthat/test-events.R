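test_that("noise-scale estimators behave per contract", {
  expect_equal(estimate_sigma(rep(2e-12, 500)), 0)
  expect_error(estimate_sigma(numeric(0)), "empty")
  set.seed(8)
  g <- rnorm(1e5)
  expect_lt(abs(estimate_sigma(g, "robust_mad") - 1), 0.02)
  expect_lt(abs(estimate_sigma(g, "global_sd") - 1), 0.02)
  # 5% contamination at +10 sigma: robust holds, plain sd blows up
  cont <- g
  cont[seq_len(5000)] <- 10
  expect_lt(abs(estimate_sigma(cont, "robust_mad") - 1), 0.1)
  expect_gt(estimate_sigma(cont, "global_sd"), 1.5)
})

test_that("threshold detection finds exactly the injected events", {
  expect_identical(nrow(detect_events(rep(0, 5000), sigma = 1,
                                      sampling_rate = 1e5)), 0L)
  # deterministic deviation: detection on noisy filtered traces is covered
  # by the benchmark recall test below
  n <- 50000
  dev <- rep(0, n)
  onsets <- round(seq(2000, 48000, length.out = 10))
  width <- 200
  tri <- 6 * c(seq(0, 1, length.out = width / 2),
               seq(1, 0, length.out = width / 2))
  for (o in onsets) dev[o:(o + width - 1)] <- dev[o:(o + width - 1)] + tri
  found <- detect_events(dev, sigma = 1, sampling_rate = 1e5)
  expect_identical(nrow(found), 10L)
  # each detected interval contains its injected peak
  expect_true(all(found$start_idx <= onsets + width / 2 &
                    found$end_idx >= onsets + width / 2))
  # disjoint and sorted
  expect_true(all(found$start_idx[-1] >= found$end_idx[-10]))
  expect_true(all(found$start_idx < found$peak_idx &
                    found$peak_idx < found$end_idx))
  # a 2-sigma bump never reaches the 3-sigma rule
  dev2 <- rep(0, n)
  dev2[20000:20199] <- 2 * tri / 6
  found2 <- detect_events(dev2, sigma = 1, sampling_rate = 1e5)
  expect_identical(nrow(found2), 0L)
})

test_that("edge-region events and sub-minimum dwells are discarded", {
  dev <- rep(0, 20000)
  dev[100:160] <- 5   # inside the edge-exclusion zone
  dev[10000:10060] <- 5
  dev[15000:15002] <- 5 # 3 samples < default 5-sample minimum
  found <- detect_events(dev, sigma = 1, sampling_rate = 1e5,
                         edge_exclude = 2400L)
  expect_identical(nrow(found), 1L)
  expect_identical(found$start_idx, 10000L)
})

test_that("features of an ideal triangular event match closed forms", {
  rate <- 1e5
  n <- 4000
  d <- 2e-3  # seconds
  a <- 1e-10 # amperes
  I0 <- 1e-9
  m <- d * rate
  dev <- rep(0, n)
  up <- seq(0, a, length.out = m / 2 + 1)
  dev[1000:(1000 + m)] <- c(up, rev(up)[-1])
  trace <- current_trace(I0 - dev, rate)
  baseline <- structure(list(baseline = rep(I0, n), deviation = dev,
                             side_points = 0L, poly_order = 1,
                             sampling_rate = rate),
                        class = "baseline_model")
  bounds <- data.frame(start_idx = 1000L, peak_idx = 1000L + as.integer(m / 2),
                       end_idx = 1001L + as.integer(m))
  f <- extract_features(trace, baseline, bounds)
  expect_identical(nrow(f), 1L)
  expect_equal(f$rel_blockade, a / I0, tolerance = 1e-12)
  expect_equal(f$dwell_s, d, tolerance = 1e-2)
  expect_equal(f$auc, a * d / 2, tolerance = 1e-2)
  expect_equal(f$left_slope, 2 * a / d, tolerance = 1e-6)
  expect_equal(f$right_slope, -2 * a / d, tolerance = 1e-6)
  # symmetric pulse: slopes mirror
  expect_equal(f$left_slope, -f$right_slope, tolerance = 1e-9)

  # doubling all currents leaves relative features fixed, scales absolute ones
  trace2 <- current_trace(2 * trace$current, rate)
  baseline2 <- baseline
  baseline2$baseline <- 2 * baseline$baseline
  baseline2$deviation <- 2 * baseline$deviation
  f2 <- extract_features(trace2, baseline2, bounds)
  expect_equal(f2$rel_blockade, f$rel_blockade, tolerance = 1e-12)
  expect_equal(f2$dwell_s, f$dwell_s)
  expect_equal(f2$auc, 2 * f$auc, tolerance = 1e-12)
  expect_equal(f2$left_slope, 2 * f$left_slope, tolerance = 1e-12)
  expect_equal(f2$right_slope, 2 * f$right_slope, tolerance = 1e-12)
})

test_that("events without a fittable flank are discarded with a reason", {
  rate <- 1e5
  dev <- rep(0, 1000)
  dev[500] <- 5 # single-sample spike: no flank span
  trace <- current_trace(1e-9 - dev * 1e-12, rate)
  baseline <- structure(list(baseline = rep(1e-9, 1000),
                             deviation = dev * 1e-12, side_points = 0L,
                             poly_order = 1, sampling_rate = rate),
                        class = "baseline_model")
  bounds <- data.frame(start_idx = 500L, peak_idx = 500L, end_idx = 501L)
  f <- extract_features(trace, baseline, bounds)
  expect_identical(nrow(f), 0L)
  expect_identical(nrow(attr(f, "discarded")), 1L)
  expect_match(attr(f, "discarded")$reason, "flank")
})

test_that("the benchmark recovers injected events with high recall", {
  fx <- benchmark_fixture()
  rs <- recovery_summary(fx$dataset, fx$features)
  expect_true(all(rs$recall >= 0.95))
  # relative blockade alone recovers within 10% for most events (pooled)
  rb <- c()
  for (lab in names(fx$dataset$traces)) {
    fl <- fx$features[fx$features$label == lab, ]
    tr <- fx$dataset$truth[fx$dataset$truth$label == lab, ]
    m <- match_events(fl, tr)
    ok <- !is.na(m)
    rb <- c(rb, abs(fl$rel_blockade[m[ok]] / tr$rel_amplitude[ok] - 1))
  }
  expect_gt(mean(rb <= 0.1), 0.9)
})
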