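#' Write a current trace to TSV
#'
#' Two-column TSV (`time_s`, `current_A`) with `#`-prefixed header lines
#' carrying the sampling rate and a configuration fingerprint. Lossless to
#' full double precision.
#'
#' @param trace A [current_trace()].
#' @param path Output file path.
#' @param config Optional object whose fingerprint is recorded in the header.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, config = NULL) {
  stopifnot(inherits(trace, "current_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# sampling_rate_hz: %.15g", trace$sampling_rate),
               sprintf("# start_time_s: %.15g", trace$start_time),
               sprintf("# config_hash: %s",
                       config_hash(config %||% trace$sampling_rate)),
               "time_s\tcurrent_A"), con)
  t <- trace$start_time + (seq_along(trace$current) - 1) / trace$sampling_rate
  writeLines(paste(sprintf("%.17g", t), sprintf("%.17g", trace$current),
                   sep = "\t"), con)
  invisible(path)
}

read_header_meta <- function(lines) {
  meta <- list()
  for (l in lines) {
    m <- regmatches(l, regexec("^#\\s*([A-Za-z0-9_.]+):\\s*(.+)$", l))[[1L]]
    if (length(m) == 3L) meta[[m[2L]]] <- m[3L]
  }
  meta
}

#' Read a current trace from TSV
#'
#' Reads either the two-column dialect (`time_s` plus one current column) or
#' a single current column with the sampling rate taken from a
#' `# sampling_rate_hz:` header line or the `sampling_rate` argument. The
#' current column name must carry its unit (`current_A`, `current_nA` or
#' `current_pA`); values are normalized to amperes. Timestamps are validated
#' for uniform sampling (jitter below 1e-6 of the sampling interval);
#' the first offending line is reported otherwise.
#'
#' @param path Input file path.
#' @param dialect `"auto"`, `"tsv_two_column"` or `"single_column_with_rate"`.
#' @param sampling_rate Sampling rate (Hz) for the single-column dialect when
#'   not present in the header.
#' @return A [current_trace()].
#' @export
read_trace <- function(path,
                       dialect = c("auto", "tsv_two_column",
                                   "single_column_with_rate"),
                       sampling_rate = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_domain("no such file: ", path)
  lines <- readLines(path)
  is_comment <- startsWith(lines, "#")
  meta <- read_header_meta(lines[is_comment])
  body_start <- which(!is_comment)[1L]
  header <- strsplit(lines[body_start], "\t", fixed = TRUE)[[1L]]
  dat <- utils::read.table(text = lines[!is_comment], header = TRUE,
                           sep = "\t")
  n_cols <- length(header)
  if (dialect == "auto") {
    dialect <- if (n_cols >= 2L) "tsv_two_column" else "single_column_with_rate"
  }

  unit_scale <- function(colname) {
    unit <- sub("^current_", "", colname)
    scale <- c(A = 1, nA = 1e-9, pA = 1e-12)[unit]
    if (!startsWith(colname, "current_") || is.na(scale)) {
      stop_domain("unknown current unit in column '", colname,
                  "' (expected current_A, current_nA or current_pA)")
    }
    unname(scale)
  }

  if (dialect == "tsv_two_column") {
    if (n_cols < 2L || header[1L] != "time_s") {
      stop_domain("two-column dialect requires columns time_s and current_<unit>")
    }
    t <- dat[[1L]]
    cur <- dat[[2L]] * unit_scale(header[2L])
    if (length(t) < 2L) stop_domain("trace must have at least 2 samples")
    dt <- stats::median(diff(t))
    if (dt <= 0) stop_domain("timestamps must be increasing")
    jitter <- abs(diff(t) - dt)
    bad <- which(jitter > 1e-6 * dt)
    if (length(bad)) {
      stop_domain(sprintf(
        "non-uniform sampling at line %d (timestamp gap %.6g s, expected %.6g s)",
        body_start + bad[1L] + 1L, t[bad[1L] + 1L] - t[bad[1L]], dt))
    }
    # endpoint average is far less sensitive to per-sample float jitter
    dt_mean <- (t[length(t)] - t[1L]) / (length(t) - 1L)
    current_trace(cur, sampling_rate = 1 / dt_mean, start_time = t[1L])
  } else {
    rate <- sampling_rate %||%
      (if (!is.null(meta$sampling_rate_hz)) as.numeric(meta$sampling_rate_hz)
       else NULL)
    if (is.null(rate)) {
      stop_domain("single-column dialect needs a sampling rate ",
                  "(header '# sampling_rate_hz:' or sampling_rate argument)")
    }
    cur <- dat[[1L]] * unit_scale(header[1L])
    start <- if (!is.null(meta$start_time_s)) as.numeric(meta$start_time_s) else 0
    current_trace(cur, sampling_rate = rate, start_time = start)
  }
}

#' Write an event feature table to TSV
#'
#' Columns: `event_id`, `start_s`, `end_s`, `dwell_ms`, `rel_blockade`,
#' `auc_A_s`, `left_slope_A_per_s`, `right_slope_A_per_s`, `local_I0_A` and,
#' when present, `label`. Dwell times are reported in milliseconds, the
#' conventional display unit; all other quantities stay in SI.
#'
#' @param features Feature table from [extract_features()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(features, path) {
  out <- data.frame(event_id = features$event_id,
                    start_s = features$start_s,
                    end_s = features$end_s,
                    dwell_ms = features$dwell_s * 1e3,
                    rel_blockade = features$rel_blockade,
                    auc_A_s = features$auc,
                    left_slope_A_per_s = features$left_slope,
                    right_slope_A_per_s = features$right_slope,
                    local_I0_A = features$local_I0)
  if (!is.null(features$label)) out$label <- features$label
  utils::write.table(format(out, digits = 15, scientific = NA, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an event feature table written by [write_event_table()]
#'
#' @param path Input file path.
#' @return Feature table with SI-unit columns as in [extract_features()].
#' @export
read_event_table <- function(path) {
  dat <- utils::read.table(path, header = TRUE, sep = "\t")
  out <- data.frame(event_id = dat$event_id,
                    start_s = dat$start_s,
                    end_s = dat$end_s,
                    dwell_s = dat$dwell_ms / 1e3,
                    rel_blockade = dat$rel_blockade,
                    auc = dat$auc_A_s,
                    left_slope = dat$left_slope_A_per_s,
                    right_slope = dat$right_slope_A_per_s,
                    local_I0 = dat$local_I0_A)
  if (!is.null(dat$label)) out$label <- dat$label
  out
}
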