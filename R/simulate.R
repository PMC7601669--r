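#' Simulation settings for synthetic nanopore recordings
#'
#' Describes the open-pore conditions emulated by the trace generator: a
#' baseline current set by the pore conductance times the applied voltage,
#' slow baseline drift (sinusoid plus random walk), and white Gaussian noise.
#'
#' @param sampling_rate Sampling rate (Hz). Default 1e5 (100 kHz).
#' @param duration Trace duration (s), or `NULL` to let
#'   [make_benchmark_dataset()] size the trace to its event load.
#' @param voltage Applied bias (V). Default 0.5.
#' @param kappa Electrolyte conductivity (S/m). Default 10.
#' @param geometry A [pore_geometry()]; default is a 3 nm tip / 200 nm base /
#'   13 um pore.
#' @param baseline_current Open-pore current (A); `NULL` (default) computes
#'   `pore_conductance(kappa, geometry) * voltage`.
#' @param noise_sigma Gaussian noise standard deviation (A). The default,
#'   1.5e-12, is one tenth of the central event depth under the default pore,
#'   conductivity and voltage (0.085 x 181 pA).
#' @param drift_amplitude,drift_period Sinusoidal baseline drift amplitude (A)
#'   and period (s).
#' @param drift_rw_sd Per-sample standard deviation of the random-walk drift
#'   component (A).
#' @param seed Integer seed making the generator bit-reproducible.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(sampling_rate = 1e5, duration = NULL,
                              voltage = 0.5, kappa = 10,
                              geometry = pore_geometry(3e-9, 200e-9, 13e-6),
                              baseline_current = NULL,
                              noise_sigma = 1.5e-12,
                              drift_amplitude = 2e-12, drift_period = 5,
                              drift_rw_sd = 2e-15, seed = 1L) {
  if (sampling_rate <= 0) stop_domain("sampling_rate must be > 0")
  if (!is.null(duration) && duration <= 0) stop_domain("duration must be > 0")
  if (noise_sigma < 0) stop_domain("noise_sigma must be >= 0")
  if (is.null(baseline_current)) {
    baseline_current <- pore_conductance(kappa, geometry) * voltage
  }
  structure(list(sampling_rate = sampling_rate, duration = duration,
                 voltage = voltage, kappa = kappa, geometry = geometry,
                 baseline_current = baseline_current,
                 noise_sigma = noise_sigma,
                 drift_amplitude = drift_amplitude,
                 drift_period = drift_period, drift_rw_sd = drift_rw_sd,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Statistical model of one sample class
#'
#' Event-population model for one analyte: a truncated-normal relative
#' blockade, a log-normal dwell time, and log-normal falling/recovering flank
#' *rates* (relative-blockade change per second). Flank rates are drawn
#' independently of both the event's depth and its dwell: the speed at which
#' the current falls or recovers is governed by the molecule's velocity
#' through the sensing zone at the pore tip, not by the total residence time
#' or the final blockade level. Each flank duration is depth / rate, stored
#' as a fraction of the dwell. Class identity is carried mostly by the flank
#' (pulse-asymmetry) medians; the blockade-depth and dwell distributions of
#' the default classes overlap heavily.
#'
#' @param label Sample name.
#' @param rel_amp_mean,rel_amp_sd Mean and sd of the relative blockade
#'   (dimensionless, truncated to `[0.02, 0.5]`).
#' @param dwell_median_s Median dwell time (s).
#' @param dwell_sdlog Log-scale sd of the dwell time (geometric sd =
#'   `exp(dwell_sdlog)`); dwells truncated to `[0.25, 8]` ms.
#' @param rise_mean,fall_mean Set the median falling (left) and recovering
#'   (right) flank rates, expressed as the flank duration of a median event
#'   as a fraction of `dwell_median_s` (so the median rate is
#'   `rel_amp_mean / (rise_mean * dwell_median_s)` per second).
#' @param frac_sdlog Log-scale sd of both flank rates.
#' @return A list of class `class_model`.
#' @export
class_model <- function(label, rel_amp_mean, rel_amp_sd,
                        dwell_median_s, dwell_sdlog,
                        rise_mean, fall_mean, frac_sdlog = 0.7) {
  stopifnot(rel_amp_mean > 0, rel_amp_mean < 1, rel_amp_sd >= 0,
            dwell_median_s > 0, dwell_sdlog >= 0,
            rise_mean > 0, fall_mean > 0, rise_mean + fall_mean < 1)
  structure(list(label = label, rel_amp_mean = rel_amp_mean,
                 rel_amp_sd = rel_amp_sd, dwell_median_s = dwell_median_s,
                 dwell_sdlog = dwell_sdlog, rise_mean = rise_mean,
                 fall_mean = fall_mean, frac_sdlog = frac_sdlog),
            class = "class_model")
}

#' Default three-class benchmark models
#'
#' Three DNA samples (short duplex `A10T10`, long duplex `A40T40`, single
#' strand `T40`) whose relative-blockade centers (0.085, 0.093, 0.066) and
#' dwell-time medians (1.07, 0.95, 1.29 ms) match the values reported for a
#' 3 nm-tip conical pore at 500 mV, so the two classical features overlap
#' heavily across classes; the classes differ mainly in pulse asymmetry
#' (falling-flank scale 0.12/0.25/0.50 versus the mirrored recovery side).
#'
#' @return Named list of three [class_model()]s.
#' @export
default_class_models <- function() {
  list(
    A10T10 = class_model("A10T10", rel_amp_mean = 0.085, rel_amp_sd = 0.025,
                         dwell_median_s = 1.07e-3, dwell_sdlog = 0.5,
                         rise_mean = 0.12, fall_mean = 0.50),
    A40T40 = class_model("A40T40", rel_amp_mean = 0.093, rel_amp_sd = 0.025,
                         dwell_median_s = 0.95e-3, dwell_sdlog = 0.5,
                         rise_mean = 0.25, fall_mean = 0.25),
    T40 = class_model("T40", rel_amp_mean = 0.066, rel_amp_sd = 0.025,
                      dwell_median_s = 1.29e-3, dwell_sdlog = 0.5,
                      rise_mean = 0.50, fall_mean = 0.12))
}

# rejection-sample `n` draws of `rfun()` until all satisfy `ok`
draw_truncated <- function(n, rfun, ok, max_iter = 1000L) {
  x <- rfun(n)
  for (iter in seq_len(max_iter)) {
    bad <- which(!ok(x))
    if (length(bad) == 0L) return(x)
    x[bad] <- rfun(length(bad))
  }
  stop_domain("truncation region too small: rejection sampling did not converge")
}

#' Draw ground-truth event specifications for one class
#'
#' Samples `n` events from a [class_model()] and places them on a trace of
#' `trace_duration` seconds so that consecutive events are separated by at
#' least `min_gap` (one Savitzky-Golay window by default) and no event
#' overlaps the edge margins. Deterministic for a fixed seed.
#'
#' @param model A [class_model()].
#' @param n Number of events, >= 0.
#' @param seed Integer seed.
#' @param trace_duration Trace length (s).
#' @param sampling_rate Sampling rate (Hz), used for the default gap.
#' @param min_gap Minimum separation between events and margin at the trace
#'   edges (s). Default one 4801-sample smoothing window.
#' @param intra_noise Extra within-event noise sd (A). Default 0.
#' @return Data frame of event specs: `onset_s`, `dwell_s`, `rel_amplitude`,
#'   `rise_fraction`, `fall_fraction`, `intra_noise`, ordered by onset.
#' @export
sample_events <- function(model, n, seed, trace_duration,
                          sampling_rate = 1e5,
                          min_gap = 4801 / sampling_rate,
                          intra_noise = 0) {
  stopifnot(inherits(model, "class_model"), n >= 0)
  empty <- data.frame(onset_s = numeric(), dwell_s = numeric(),
                      rel_amplitude = numeric(), rise_fraction = numeric(),
                      fall_fraction = numeric(), intra_noise = numeric())
  if (n == 0L) return(empty)
  if (trace_duration <= 0) stop_domain("trace_duration must be > 0")

  with_seed(seed, {
    dwell <- draw_truncated(n,
      function(k) stats::rlnorm(k, log(model$dwell_median_s), model$dwell_sdlog),
      function(x) x >= 2.5e-4 & x <= 8e-3)
    rel <- draw_truncated(n,
      function(k) stats::rnorm(k, model$rel_amp_mean, model$rel_amp_sd),
      function(x) x >= 0.02 & x <= 0.5)
    # flank rates (relative-blockade change per second) drawn independently
    # of both depth and dwell; flank duration = depth / rate, expressed as a
    # fraction of the dwell and clipped into the feasible trapezoid region
    rho_rise <- stats::rlnorm(
      n, log(model$rel_amp_mean / (model$rise_mean * model$dwell_median_s)),
      model$frac_sdlog)
    rho_fall <- stats::rlnorm(
      n, log(model$rel_amp_mean / (model$fall_mean * model$dwell_median_s)),
      model$frac_sdlog)
    rise <- pmin(pmax(rel / rho_rise / dwell, 0.02), 0.7)
    fall <- pmin(pmax(rel / rho_fall / dwell, 0.02), 0.7)
    # keep a plateau of >= 15% of the dwell
    tot <- rise + fall
    over <- tot > 0.85
    rise[over] <- rise[over] * 0.85 / tot[over]
    fall[over] <- fall[over] * 0.85 / tot[over]

    needed <- 2 * min_gap + sum(dwell) + (n - 1) * min_gap
    slack <- trace_duration - needed
    if (slack < 0) {
      stop_domain(sprintf(
        "trace of %.3g s cannot hold %d events (needs >= %.3g s)",
        trace_duration, n, needed))
    }
    # scatter the spare time over the n+1 inter-event gaps
    w <- stats::runif(n + 1L)
    extra <- slack * w / sum(w)
    steps <- if (n > 1L) dwell[seq_len(n - 1L)] + min_gap + extra[2:n] else numeric(0)
    onset <- min_gap + extra[1L] + cumsum(c(0, steps))
  })
  data.frame(onset_s = onset, dwell_s = dwell, rel_amplitude = rel,
             rise_fraction = rise, fall_fraction = fall,
             intra_noise = intra_noise)
}

#' Render a synthetic current trace from event specifications
#'
#' Builds `baseline + drift + noise` and subtracts one trapezoidal current
#' blockade per event: a linear fall over `rise_fraction * dwell`, a plateau
#' of depth `rel_amplitude * baseline_current`, and a linear recovery over
#' `fall_fraction * dwell`. The trapezoid gives every injected event
#' closed-form expected features, which is what makes parameter-recovery
#' testing possible.
#'
#' @param config A [simulation_config()] with non-`NULL` `duration`.
#' @param events Event-spec data frame from [sample_events()] (may be empty).
#' @param seed Seed for the noise/drift streams; defaults to `config$seed`.
#' @return List with `trace` (a [current_trace()]) and `truth` (the event
#'   table extended with the injected absolute `depth_A`).
#' @export
render_trace <- function(config, events, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(config$duration)) stop_domain("config$duration must be set")
  n <- round(config$duration * config$sampling_rate)
  rate <- config$sampling_rate

  if (nrow(events) > 0) {
    events <- events[order(events$onset_s), , drop = FALSE]
    ends <- events$onset_s + events$dwell_s
    if (any(events$onset_s < 0) || any(ends > config$duration)) {
      stop_domain("events extend outside the trace")
    }
    if (nrow(events) > 1L && any(events$onset_s[-1L] < ends[-nrow(events)])) {
      stop_domain("overlapping events")
    }
  }

  tt <- (seq_len(n) - 1) / rate
  cur <- with_seed(seed, {
    noise <- stats::rnorm(n, 0, config$noise_sigma)
    rw <- if (config$drift_rw_sd > 0) {
      cumsum(stats::rnorm(n, 0, config$drift_rw_sd))
    } else 0
    drift <- config$drift_amplitude * sin(2 * pi * tt / config$drift_period) + rw
    base <- config$baseline_current + drift + noise
    for (i in seq_len(nrow(events))) {
      m <- max(3L, round(events$dwell_s[i] * rate))
      i0 <- floor(events$onset_s[i] * rate) + 1L
      u <- (seq_len(m) - 0.5) / m
      depth <- events$rel_amplitude[i] * config$baseline_current
      rf <- events$rise_fraction[i]; ff <- events$fall_fraction[i]
      prof <- depth * pmin(1, pmin(u / rf, (1 - u) / ff))
      prof <- pmax(prof, 0)
      idx <- i0:(i0 + m - 1L)
      base[idx] <- base[idx] - prof
      if (events$intra_noise[i] > 0) {
        base[idx] <- base[idx] + stats::rnorm(m, 0, events$intra_noise[i])
      }
    }
    base
  })
  truth <- events
  truth$depth_A <- if (nrow(events)) {
    events$rel_amplitude * config$baseline_current
  } else numeric(0)
  list(trace = current_trace(cur, rate), truth = truth)
}

#' Labeled multi-class benchmark dataset with ground truth
#'
#' Generates one synthetic trace per class from the given [class_model()]s,
#' emulating the study conditions: overlapping relative-blockade and
#' dwell-time marginals across classes with class-informative pulse
#' asymmetry. When `config$duration` is `NULL` each trace is sized to hold
#' its events with ~5% slack beyond the 99th-percentile dwell load.
#'
#' @param models Named list of >= 2 [class_model()]s with distinct labels.
#'   Default [default_class_models()].
#' @param n_per_class Events per class.
#' @param config A [simulation_config()].
#' @param seed Master seed; per-class seeds are derived from it.
#' @return List of class `benchmark_dataset` with `traces` (named list of
#'   [current_trace()]s), `truth` (row-bound ground-truth table with a
#'   `label` column), `models`, and `config`.
#' @export
make_benchmark_dataset <- function(models = default_class_models(),
                                   n_per_class = 150,
                                   config = simulation_config(),
                                   seed = config$seed) {
  labels <- vapply(models, function(m) m$label, character(1))
  if (length(models) < 2L || anyDuplicated(labels)) {
    stop_domain("need at least two class models with distinct labels")
  }
  min_gap <- 4801 / config$sampling_rate
  traces <- list()
  truth <- list()
  for (i in seq_along(models)) {
    m <- models[[i]]
    cfg <- config
    if (is.null(cfg$duration)) {
      q99 <- min(8e-3, stats::qlnorm(0.99, log(m$dwell_median_s), m$dwell_sdlog))
      cfg$duration <- 1.05 * (2 * min_gap + n_per_class * (min_gap + q99))
    }
    ev <- sample_events(m, n_per_class, seed = seed + i,
                        trace_duration = cfg$duration,
                        sampling_rate = cfg$sampling_rate,
                        min_gap = min_gap)
    r <- render_trace(cfg, ev, seed = seed + 1000L + i)
    traces[[m$label]] <- r$trace
    if (nrow(r$truth)) r$truth$label <- m$label
    truth[[m$label]] <- r$truth
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  structure(list(traces = traces, truth = truth, models = models,
                 config = config, seed = seed),
            class = "benchmark_dataset")
}

#' Run the event pipeline over a benchmark dataset
#'
#' Applies [analyze_trace()] to every trace of a [make_benchmark_dataset()]
#' result and attaches the class label to each recovered event, giving the
#' labeled feature table used for the statistical and classification stages.
#'
#' @param dataset A `benchmark_dataset`.
#' @param ... Passed to [analyze_trace()].
#' @return A feature table (see [extract_features()]) with a `label` column;
#'   attributes `"truth"` (ground-truth table) and `"per_trace"` (list of
#'   per-trace sigma/threshold/count records).
#' @export
analyze_benchmark <- function(dataset, ...) {
  stopifnot(inherits(dataset, "benchmark_dataset"))
  feats <- list()
  per_trace <- list()
  for (lab in names(dataset$traces)) {
    f <- analyze_trace(dataset$traces[[lab]], ...)
    per_trace[[lab]] <- list(sigma = attr(f, "sigma"),
                             threshold = attr(f, "threshold"),
                             n_detected = attr(f, "n_detected"),
                             n_kept = nrow(f))
    if (nrow(f)) f$label <- lab
    feats[[lab]] <- f
  }
  out <- do.call(rbind, feats)
  rownames(out) <- NULL
  attr(out, "truth") <- dataset$truth
  attr(out, "per_trace") <- per_trace
  out
}

#' Match detected events to ground-truth events
#'
#' Pairs each injected event with the detected event (same trace) whose
#' interval overlaps more than half of the injected dwell; each detected
#' event is used at most once.
#'
#' @param features Feature table for one trace (from [analyze_trace()]).
#' @param truth Ground-truth table for the same trace.
#' @return Integer vector, one entry per truth row: the matching `features`
#'   row index, or `NA` if the event was missed.
#' @export
match_events <- function(features, truth) {
  used <- rep(FALSE, nrow(features))
  out <- rep(NA_integer_, nrow(truth))
  for (i in seq_len(nrow(truth))) {
    a <- truth$onset_s[i]; b <- a + truth$dwell_s[i]
    ov <- pmin(features$end_s, b) - pmax(features$start_s, a)
    ok <- which(!used & ov > 0.5 * truth$dwell_s[i])
    if (length(ok)) {
      j <- ok[which.max(ov[ok])]
      out[i] <- j
      used[j] <- TRUE
    }
  }
  out
}
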