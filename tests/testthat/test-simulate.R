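test_that("event sampling is deterministic, bounded and capacity-checked", {
  m <- default_class_models()$A10T10
  expect_identical(nrow(sample_events(m, 0, 1, 5)), 0L)
  a <- sample_events(m, 50, seed = 3, trace_duration = 5)
  b <- sample_events(m, 50, seed = 3, trace_duration = 5)
  expect_identical(a, b)
  expect_true(all(diff(a$onset_s) > 0))
  # non-overlap with at least one smoothing window between events
  gaps <- a$onset_s[-1] - (a$onset_s[-50] + a$dwell_s[-50])
  expect_true(all(gaps >= 4801 / 1e5 - 1e-9))
  expect_true(all(a$rise_fraction + a$fall_fraction <= 0.85 + 1e-9))
  expect_error(sample_events(m, 500, seed = 1, trace_duration = 2),
               "cannot hold")
})

test_that("sampled dwell medians track the class model", {
  m <- default_class_models()$A40T40
  ev <- sample_events(m, 200, seed = 11, trace_duration = 60)
  expect_lt(abs(median(ev$dwell_s) / m$dwell_median_s - 1), 0.15)
})

test_that("rendered traces honour the constructed geometry", {
  cfg <- simulation_config(duration = 0.2, noise_sigma = 0,
                           drift_amplitude = 0, drift_rw_sd = 0,
                           baseline_current = 10e-9)
  none <- render_trace(cfg, sample_events(default_class_models()$T40, 0, 1, 0.2))
  expect_equal(none$trace$current, rep(10e-9, 20000))
  ev <- data.frame(onset_s = 0.1, dwell_s = 2e-3, rel_amplitude = 0.1,
                   rise_fraction = 0.2, fall_fraction = 0.2, intra_noise = 0)
  one <- render_trace(cfg, ev)
  expect_equal(min(one$trace$current), 9e-9, tolerance = 1e-3)
  expect_identical(nrow(one$truth), 1L)
  # overlapping events are rejected
  two <- rbind(ev, transform(ev, onset_s = 0.101))
  expect_error(render_trace(cfg, two), "overlap")
})

test_that("rendering is bit-reproducible and unbiased off-event", {
  cfg <- simulation_config(duration = 1.5, drift_amplitude = 0,
                           drift_rw_sd = 0, seed = 9)
  ev <- sample_events(default_class_models()$A10T10, 5, 2, 1.5)
  r1 <- render_trace(cfg, ev)
  r2 <- render_trace(cfg, ev)
  expect_identical(r1$trace$current, r2$trace$current)
  # event-free stretch: mean near baseline, sd near noise_sigma
  free <- seq_len(floor(min(ev$onset_s) * 1e5) - 100L)
  expect_gt(length(free), 1e3)
  expect_lt(abs(mean(r1$trace$current[free]) - cfg$baseline_current),
            3 * cfg$noise_sigma / sqrt(length(free)) + 1e-18)
  n_all <- length(r1$trace$current)
  expect_gt(n_all, 1e5)
  off <- rep(TRUE, n_all)
  for (i in seq_len(nrow(ev))) {
    idx <- floor(ev$onset_s[i] * 1e5):ceiling((ev$onset_s[i] + ev$dwell_s[i]) * 1e5)
    off[idx] <- FALSE
  }
  expect_lt(abs(sd(r1$trace$current[off]) / cfg$noise_sigma - 1), 0.1)
})

test_that("benchmark dataset carries full ground truth and overlaps heavily", {
  fx <- benchmark_fixture()
  ds <- fx$dataset
  expect_identical(sort(names(ds$traces)), c("A10T10", "A40T40", "T40"))
  expect_identical(nrow(ds$truth), 3L * 120L)
  expect_error(make_benchmark_dataset(default_class_models()[1], 10),
               "two class")
  # the two classical features overlap across all class pairs
  labs <- unique(ds$truth$label)
  for (i in 1:2) for (j in (i + 1):3) {
    ov <- histogram_overlap(ds$truth$rel_amplitude[ds$truth$label == labs[i]],
                            ds$truth$rel_amplitude[ds$truth$label == labs[j]],
                            bin_width = 0.01)
    expect_gt(ov, 0.5)
  }
  # empty dataset keeps a valid schema
  empty <- make_benchmark_dataset(n_per_class = 0,
                                  config = simulation_config(duration = 1))
  expect_identical(nrow(empty$truth), 0L)
  expect_true(all(c("onset_s", "dwell_s", "rel_amplitude") %in%
                    names(empty$truth)))
})
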