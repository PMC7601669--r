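#' End-to-end analysis pipeline
#'
#' Runs the full analysis in the standard order — low-pass filter,
#' baseline correction, 3-sigma detection, five-feature extraction,
#' distribution/correlation/regression diagnostics and (optionally) the
#' paired two- vs five-feature SVM comparison — on either synthetic traces
#' or trace files, and returns all stage outputs plus a reproducibility
#' manifest.
#'
#' `config` is a nested list with blocks:
#' \describe{
#'   \item{simulate}{`list(n_per_class, seed, models = NULL, sim = NULL)` —
#'     generate a benchmark dataset ([make_benchmark_dataset()]); `sim` is a
#'     [simulation_config()].}
#'   \item{traces}{Named character vector of trace file paths (names are used
#'     as class labels). Exactly one of `simulate`/`traces` must be given.}
#'   \item{filter}{`list(cutoff = 2500, order = 2)`.}
#'   \item{baseline}{`list(side_points = 2400, poly_order = 1)`.}
#'   \item{detect}{Arguments for [detection_config()] (k_detect = 3, ...).}
#'   \item{classify}{`list(folds = 5, seed = 1)`, or omit the block to stop
#'     after the statistics stage.}
#' }
#'
#' @param config Pipeline configuration list.
#' @return Object of class `poretrace_run`: list with `features` (labeled
#'   event table), `stats` (per-class correlation matrices, regressions, and
#'   the two standard histograms), `classification` (a
#'   [compare_feature_sets()] result or `NULL`), and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config))
  filt <- utils::modifyList(list(cutoff = 2500, order = 2),
                            config$filter %||% list())
  base <- utils::modifyList(list(side_points = 2400, poly_order = 1),
                            config$baseline %||% list())
  det <- do.call(detection_config, config$detect %||% list())

  manifest <- list(
    package = "poretrace",
    version = as.character(utils::packageVersion("poretrace")),
    config = config, config_hash = config_hash(config), stages = list())
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(errorCondition(
        sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
        class = "poretrace_stage_error",
        manifest = manifest))
    })
  }

  # --- input stage -----------------------------------------------------
  if (!is.null(config$simulate) && !is.null(config$traces)) {
    stop_domain("give either a 'simulate' or a 'traces' block, not both")
  }
  truth <- NULL
  traces <- run_stage("input", {
    if (!is.null(config$simulate)) {
      sim <- config$simulate
      ds <- make_benchmark_dataset(
        models = sim$models %||% default_class_models(),
        n_per_class = sim$n_per_class %||% 150,
        config = sim$sim %||% simulation_config(),
        seed = sim$seed %||% 1L)
      truth <- ds$truth
      manifest$stages$input <- list(
        kind = "simulate", seed = ds$seed,
        n_truth_events = nrow(ds$truth))
      ds$traces
    } else if (!is.null(config$traces)) {
      paths <- config$traces
      if (is.null(names(paths)) || any(names(paths) == "")) {
        stop_domain("'traces' must be a named vector (names = class labels)")
      }
      manifest$stages$input <- list(kind = "files", paths = unname(paths))
      lapply(paths, read_trace)
    } else {
      stop_domain("config needs a 'simulate' or 'traces' block")
    }
  })

  # --- filter / baseline / detect / features ---------------------------
  features <- run_stage("events", {
    out <- list()
    per_trace <- list()
    for (lab in names(traces)) {
      f <- analyze_trace(traces[[lab]], cutoff = filt$cutoff,
                         filter_order = filt$order,
                         side_points = base$side_points,
                         poly_order = base$poly_order, config = det)
      per_trace[[lab]] <- list(
        sigma_A = attr(f, "sigma"), threshold_A = attr(f, "threshold"),
        n_detected = attr(f, "n_detected"), n_kept = nrow(f),
        n_discarded = nrow(attr(f, "discarded")))
      if (nrow(f)) f$label <- lab
      out[[lab]] <- f
    }
    manifest$stages$events <- per_trace
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })

  # --- statistics ------------------------------------------------------
  stats_out <- run_stage("stats", {
    by_label <- split(features, features$label)
    list(
      correlation_pooled = correlation_matrix(features),
      correlations = lapply(by_label, correlation_matrix),
      regressions = lapply(by_label, regress_blockade_on_dwell),
      histograms = list(
        rel_blockade = lapply(by_label, function(d)
          density_histogram(d$rel_blockade, bin_width = 0.01)),
        dwell = lapply(by_label, function(d)
          density_histogram(d$dwell_s, bin_width = 200e-6))))
  })
  manifest$stages$stats <- list(n_classes = length(stats_out$correlations))

  # --- classification (optional) ---------------------------------------
  classification <- NULL
  if (!is.null(config$classify)) {
    classification <- run_stage("classify", {
      cls <- config$classify
      compare_feature_sets(features, features$label,
                           folds = cls$folds %||% 5,
                           seed = cls$seed %||% 1L)
    })
    manifest$stages$classify <- list(
      folds = classification$two$folds,
      accuracy_two = classification$two$accuracy,
      accuracy_five = classification$five$accuracy)
  }

  structure(list(features = features, truth = truth, stats = stats_out,
                 classification = classification, manifest = manifest),
            class = "poretrace_run")
}

#' @export
print.poretrace_run <- function(x, ...) {
  cat(sprintf("poretrace run: %d events across %d classes\n",
              nrow(x$features), length(unique(x$features$label))))
  for (lab in names(x$stats$regressions)) {
    r <- x$stats$regressions[[lab]]
    cat(sprintf("  %s: n = %d, R^2(rel_blockade ~ dwell) = %.3f\n",
                lab, r$n, r$r_squared))
  }
  if (!is.null(x$classification)) print(x$classification)
  invisible(x)
}
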