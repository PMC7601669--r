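#' Event-detection configuration
#'
#' Parameters for threshold-based blockade detection on the deviation series
#' (`baseline - current`, positive during blockades). An event is any maximal
#' region above `k_boundary * sigma` that contains at least one sample above
#' `k_detect * sigma`; the inner threshold defaults to the 3-sigma rule, the
#' outer boundary to 1 sigma so the flanks needed for slope fits are kept.
#'
#' @param k_detect Detection threshold multiplier. Default 3.
#' @param k_boundary Boundary multiplier ending an event (must satisfy
#'   `0 < k_boundary < k_detect`). Default 1.
#' @param sigma_method Noise scale estimator: `"robust_mad"` (1.4826 x median
#'   absolute deviation, insensitive to the events themselves) or
#'   `"global_sd"` (plain standard deviation). Default `"robust_mad"`.
#' @param min_dwell Minimum event duration (s); events shorter than this are
#'   discarded. `NULL` (default) means 5 samples at the trace sampling rate.
#' @param merge_gap Events separated by less than this gap (s) are merged.
#'   Default 0 (no merging).
#' @return A list of class `detection_config`.
#' @export
detection_config <- function(k_detect = 3, k_boundary = 1,
                             sigma_method = c("robust_mad", "global_sd"),
                             min_dwell = NULL, merge_gap = 0) {
  sigma_method <- match.arg(sigma_method)
  if (!(k_detect > k_boundary && k_boundary > 0)) {
    stop_domain("need k_detect > k_boundary > 0")
  }
  if (!is.null(min_dwell) && min_dwell < 0) stop_domain("min_dwell must be >= 0")
  if (merge_gap < 0) stop_domain("merge_gap must be >= 0")
  structure(list(k_detect = k_detect, k_boundary = k_boundary,
                 sigma_method = sigma_method, min_dwell = min_dwell,
                 merge_gap = merge_gap),
            class = "detection_config")
}

#' Noise scale of a deviation series
#'
#' Estimates the noise standard deviation used by the 3-sigma detection rule.
#' The robust estimator (1.4826 x median absolute deviation) is nearly
#' unaffected by the blockade events present in the series, whereas the plain
#' standard deviation is inflated by them.
#'
#' @param deviation Numeric series (A).
#' @param method `"robust_mad"` or `"global_sd"`.
#' @return Estimated sigma (A).
#' @export
estimate_sigma <- function(deviation,
                           method = c("robust_mad", "global_sd")) {
  method <- match.arg(method)
  if (length(deviation) == 0L) stop_domain("empty deviation series")
  if (anyNA(deviation)) stop_domain("deviation contains NA")
  switch(method,
         robust_mad = stats::mad(deviation, constant = 1.4826),
         global_sd = stats::sd(deviation))
}

#' Detect current-blockade events by threshold crossing
#'
#' Flags every maximal run of the deviation series above
#' `k_boundary * sigma` that contains a crossing of `k_detect * sigma`
#' (the 3-sigma rule by default). Runs closer than `merge_gap` are merged;
#' runs shorter than `min_dwell` and runs overlapping the edge-affected
#' first/last `edge_exclude` samples are discarded. Returned events are
#' sorted and disjoint.
#'
#' @param deviation Deviation series (`baseline - current`, A).
#' @param sigma Noise scale (A), > 0; see [estimate_sigma()].
#' @param config A [detection_config()].
#' @param sampling_rate Sampling rate (Hz), used to convert the duration
#'   parameters to samples.
#' @param edge_exclude Number of edge samples at each end of the trace whose
#'   overlap disqualifies an event (typically the Savitzky-Golay
#'   `side_points`). Default 0.
#' @return A data frame with one row per event: `start_idx`, `peak_idx`,
#'   `end_idx` (1-based, half-open `[start_idx, end_idx)`), where `peak_idx`
#'   is the sample of maximum deviation.
#' @export
detect_events <- function(deviation, sigma, config = detection_config(),
                          sampling_rate, edge_exclude = 0L) {
  stopifnot(inherits(config, "detection_config"), is.numeric(deviation))
  if (!is.finite(sigma) || sigma <= 0) stop_domain("sigma must be > 0")
  if (missing(sampling_rate) || sampling_rate <= 0) {
    stop_domain("sampling_rate must be > 0")
  }
  n <- length(deviation)
  empty <- data.frame(start_idx = integer(), peak_idx = integer(),
                      end_idx = integer())
  if (n == 0L) return(empty)

  above <- deviation >= config$k_boundary * sigma
  r <- rle(above)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  cand <- which(r$values)
  if (length(cand) == 0L) return(empty)

  # keep only boundary runs that contain a detection-threshold crossing
  run_id <- rep.int(seq_along(r$lengths), r$lengths)
  hot <- unique(run_id[deviation >= config$k_detect * sigma])
  cand <- cand[cand %in% hot]
  if (length(cand) == 0L) return(empty)
  starts <- run_start[cand]
  ends <- run_end[cand] + 1L # half-open

  # merge events separated by < merge_gap
  gap_samples <- round(config$merge_gap * sampling_rate)
  if (gap_samples > 0L && length(starts) > 1L) {
    keep_start <- starts[1L]
    ms <- integer(0); me <- integer(0)
    cur_end <- ends[1L]
    for (i in seq_along(starts)[-1L]) {
      if (starts[i] - cur_end < gap_samples) {
        cur_end <- ends[i]
      } else {
        ms <- c(ms, keep_start); me <- c(me, cur_end)
        keep_start <- starts[i]; cur_end <- ends[i]
      }
    }
    starts <- c(ms, keep_start); ends <- c(me, cur_end)
  }

  min_dwell <- config$min_dwell %||% (5 / sampling_rate)
  keep <- (ends - starts) / sampling_rate >= min_dwell
  if (edge_exclude > 0L) {
    keep <- keep & starts > edge_exclude & ends <= n - edge_exclude + 1L
  }
  starts <- starts[keep]; ends <- ends[keep]
  if (length(starts) == 0L) return(empty)

  peaks <- vapply(seq_along(starts), function(i) {
    seg <- starts[i]:(ends[i] - 1L)
    seg[which.max(deviation[seg])]
  }, integer(1))
  data.frame(start_idx = starts, peak_idx = peaks, end_idx = ends)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Five-feature characterization of detected events
#'
#' Computes, for each detected blockade, the five standard resistive-pulse
#' descriptors: dwell time `dwell_s` (event duration), relative blockade
#' `rel_blockade` (peak deviation over the local baseline current), event area
#' `auc` (trapezoidal integral of the deviation, A s), and the left/right
#' flank slopes `left_slope` / `right_slope` (A/s): least-squares line fits of
#' the deviation over the central 10-90% span of each flank (the rise-time
#' convention), i.e. from the first sample at >= 10% of the peak deviation to
#' the first at >= 90% for the falling flank, and mirrored for the recovering
#' flank. Fitting the central flank rather than start-to-argmax keeps the
#' slopes tied to the flank steepness: on a noisy flat-topped event the
#' deviation argmax lands anywhere on the plateau, so a fit spanning a random
#' plateau stretch measures mostly where the noise peaked; and the 10% lower
#' bound excludes the shallow smeared foot that the low-pass filter adds
#' below the detection boundary. Under the deviation sign convention
#' the left slope is positive and the right slope negative. Events without at
#' least two samples on each flank are discarded and reported in the
#' `"discarded"` attribute.
#'
#' @param trace The (filtered) [current_trace()].
#' @param baseline The matching [estimate_baseline_savgol()] result.
#' @param bounds Data frame from [detect_events()].
#' @return A data frame with one row per retained event: `event_id`,
#'   `start_s`, `end_s`, `dwell_s`, `rel_blockade`, `auc`, `left_slope`,
#'   `right_slope`, `local_I0`. Attribute `"discarded"` is a data frame of
#'   dropped events with a `reason` column.
#' @export
extract_features <- function(trace, baseline, bounds) {
  stopifnot(inherits(trace, "current_trace"),
            inherits(baseline, "baseline_model"))
  stopifnot(all(c("start_idx", "peak_idx", "end_idx") %in% names(bounds)))
  rate <- trace$sampling_rate
  dt <- 1 / rate
  dev <- baseline$deviation
  t0 <- trace$start_time

  rows <- vector("list", nrow(bounds))
  dropped <- list()
  for (i in seq_len(nrow(bounds))) {
    s <- bounds$start_idx[i]; p <- bounds$peak_idx[i]; e <- bounds$end_idx[i]
    seg <- s:(e - 1L)
    # 10-90% flank spans on each side of the plateau
    hi <- seg[dev[seg] >= 0.9 * dev[p]]
    lo <- seg[dev[seg] >= 0.1 * dev[p]]
    l_start <- lo[1L]; l_end <- hi[1L]
    r_start <- hi[length(hi)]; r_end <- lo[length(lo)]
    if (l_end - l_start < 1L || r_end - r_start < 1L) {
      dropped[[length(dropped) + 1L]] <- data.frame(
        start_idx = s, peak_idx = p, end_idx = e,
        reason = if (l_end - l_start < 1L) "no_left_flank" else "no_right_flank")
      next
    }
    i0 <- baseline$baseline[p]
    rows[[i]] <- data.frame(
      start_s = t0 + (s - 1L) * dt,
      end_s = t0 + (e - 1L) * dt,
      dwell_s = (e - s) * dt,
      rel_blockade = dev[p] / i0,
      auc = trapz_uniform(dev[seg], dt),
      left_slope = ls_slope(dev[l_start:l_end], dt),
      right_slope = ls_slope(dev[r_start:r_end], dt),
      local_I0 = i0)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(start_s = numeric(), end_s = numeric(),
                      dwell_s = numeric(), rel_blockade = numeric(),
                      auc = numeric(), left_slope = numeric(),
                      right_slope = numeric(), local_I0 = numeric())
  }
  out <- cbind(event_id = seq_len(nrow(out)), out)
  attr(out, "discarded") <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(start_idx = integer(), peak_idx = integer(),
               end_idx = integer(), reason = character())
  out
}

#' Full single-trace event analysis
#'
#' Convenience driver applying the standard processing order to one raw
#' trace: Butterworth low-pass filter, Savitzky-Golay baseline correction,
#' noise estimation, threshold detection, and five-feature extraction.
#'
#' @param trace A raw [current_trace()].
#' @param cutoff,filter_order Low-pass settings; see [lowpass_butterworth()].
#' @param side_points,poly_order Baseline settings; see
#'   [estimate_baseline_savgol()].
#' @param config A [detection_config()].
#' @return The feature table of [extract_features()], with attributes
#'   `"sigma"` (noise estimate, A), `"threshold"` (detection threshold, A),
#'   and `"n_detected"` (events before feature-stage discards).
#' @export
analyze_trace <- function(trace, cutoff = 2500, filter_order = 2,
                          side_points = 2400, poly_order = 1,
                          config = detection_config()) {
  filtered <- lowpass_butterworth(trace, cutoff = cutoff, order = filter_order)
  bl <- estimate_baseline_savgol(filtered, side_points = side_points,
                                 poly_order = poly_order)
  sigma <- estimate_sigma(bl$deviation, config$sigma_method)
  bounds <- detect_events(bl$deviation, sigma, config,
                          sampling_rate = trace$sampling_rate,
                          edge_exclude = side_points)
  feats <- extract_features(filtered, bl, bounds)
  attr(feats, "sigma") <- sigma
  attr(feats, "threshold") <- config$k_detect * sigma
  attr(feats, "n_detected") <- nrow(bounds)
  feats
}
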