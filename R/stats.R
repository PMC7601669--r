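#' Density-normalized histogram
#'
#' Histogram whose bar heights are densities `d_i = f_i / (n * w_i)`, where
#' `f_i` is the count in bin `i`, `n` the total sample size and `w_i` the bin
#' width, so that `sum(d_i * w_i) = 1` when every sample falls inside the
#' binned range. Bins are left-closed, right-open and anchored at 0 (the
#' event features all have positive support). Conventional widths are 0.01
#' for the relative blockade and 200 us for the dwell time.
#'
#' @param values Numeric sample, non-empty.
#' @param bin_width Common bin width, > 0.
#' @param range Optional `c(lo, hi)`; defaults to bins anchored at 0 covering
#'   the data. Values outside the range are not counted but still contribute
#'   to `n`.
#' @return Object of class `density_histogram`: list with `bin_edges`,
#'   `counts`, `n`, `bin_width`, `density`.
#' @export
density_histogram <- function(values, bin_width, range = NULL) {
  if (length(values) == 0L) stop_domain("empty input")
  if (!is.numeric(bin_width) || bin_width <= 0) {
    stop_domain("bin_width must be > 0")
  }
  n <- length(values)
  if (is.null(range)) {
    lo <- min(0, floor(min(values) / bin_width) * bin_width)
    hi <- ceiling(max(values) / bin_width + 1e-9) * bin_width
  } else {
    lo <- range[1L]; hi <- range[2L]
  }
  edges <- seq(lo, hi, by = bin_width)
  if (edges[length(edges)] < hi) edges <- c(edges, edges[length(edges)] + bin_width)
  # left-closed right-open bins
  bin <- findInterval(values, edges, rightmost.closed = FALSE)
  inside <- bin >= 1L & bin <= length(edges) - 1L & values < edges[length(edges)]
  counts <- tabulate(bin[inside], nbins = length(edges) - 1L)
  structure(list(bin_edges = edges, counts = counts, n = n,
                 bin_width = bin_width, density = counts / (n * bin_width)),
            class = "density_histogram")
}

#' Overlap coefficient of two histogram densities
#'
#' Intersection of the two density-normalized histograms computed on a shared
#' binning: `sum(pmin(d_a, d_b) * w)`. 1 means identical binned
#' distributions, 0 means disjoint support.
#'
#' @param a,b Numeric samples.
#' @param bin_width Shared bin width.
#' @return Overlap in `[0, 1]`.
#' @export
histogram_overlap <- function(a, b, bin_width) {
  lo <- min(0, floor(min(a, b) / bin_width) * bin_width)
  hi <- ceiling(max(a, b) / bin_width + 1e-9) * bin_width
  ha <- density_histogram(a, bin_width, range = c(lo, hi))
  hb <- density_histogram(b, bin_width, range = c(lo, hi))
  sum(pmin(ha$density, hb$density)) * bin_width
}

#' Pearson correlation matrix of the event features
#'
#' Correlation matrix over the five event descriptors (or any chosen numeric
#' columns). Zero-variance columns yield `NA` entries and a warning naming
#' the column, never a silent 0.
#'
#' @param table Feature table (data frame).
#' @param columns Columns to correlate; defaults to the five event features.
#' @return Symmetric correlation matrix with unit diagonal (where defined).
#' @export
correlation_matrix <- function(table,
                               columns = c("rel_blockade", "dwell_s", "auc",
                                           "left_slope", "right_slope")) {
  stopifnot(all(columns %in% names(table)))
  if (nrow(table) < 3L) stop_domain("need at least 3 events")
  m <- as.matrix(table[columns])
  if (any(!is.finite(m))) stop_domain("non-finite feature values")
  sds <- apply(m, 2L, stats::sd)
  flat <- sds == 0
  if (any(flat)) {
    warning("zero-variance column(s): ", paste(columns[flat], collapse = ", "),
            "; correlations reported as NA", call. = FALSE)
  }
  cc <- suppressWarnings(stats::cor(m))
  cc[flat, ] <- NA_real_
  cc[, flat] <- NA_real_
  diag(cc)[!flat] <- 1
  cc
}

#' Linear regression of relative blockade on dwell time
#'
#' Ordinary least squares with the relative blockade as response and the
#' dwell time as predictor. The reported R-squared equals the squared
#' Pearson correlation of the two columns.
#'
#' @param table Feature table with `rel_blockade` and `dwell_s` columns.
#' @return Object of class `regression_result`: list with `slope`,
#'   `intercept`, `r_squared`, `n`.
#' @export
regress_blockade_on_dwell <- function(table) {
  stopifnot(all(c("rel_blockade", "dwell_s") %in% names(table)))
  if (nrow(table) < 3L) stop_domain("need at least 3 events")
  if (stats::sd(table$dwell_s) == 0) stop_domain("constant predictor dwell_s")
  fit <- stats::lm(rel_blockade ~ dwell_s, data = table)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = summary(fit)$r.squared,
                 n = nrow(table)),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("OLS rel_blockade ~ dwell: slope = %.4g, R^2 = %.3f (n = %d)\n",
              x$slope, x$r_squared, x$n))
  invisible(x)
}
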