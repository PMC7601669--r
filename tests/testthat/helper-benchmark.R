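# Shared synthetic benchmark, generated once per test run.
.benchmark_env <- new.env(parent = emptyenv())

benchmark_fixture <- function(n_per_class = 120, seed = 42) {
  key <- sprintf("b%d_%d", n_per_class, seed)
  if (is.null(.benchmark_env[[key]])) {
    ds <- make_benchmark_dataset(n_per_class = n_per_class, seed = seed)
    .benchmark_env[[key]] <- list(dataset = ds, features = analyze_benchmark(ds))
  }
  .benchmark_env[[key]]
}

# Per-class detection recall and fraction of matched events whose relative
# blockade and dwell are both within `tol` of the injected values.
recovery_summary <- function(dataset, features, tol = 0.1) {
  recall <- recovered <- numeric(0)
  for (lab in names(dataset$traces)) {
    fl <- features[features$label == lab, ]
    tr <- dataset$truth[dataset$truth$label == lab, ]
    m <- match_events(fl, tr)
    ok <- !is.na(m)
    dw <- abs(fl$dwell_s[m[ok]] / tr$dwell_s[ok] - 1)
    rb <- abs(fl$rel_blockade[m[ok]] / tr$rel_amplitude[ok] - 1)
    recall <- c(recall, mean(ok))
    recovered <- c(recovered, mean(dw <= tol & rb <= tol))
  }
  list(recall = recall, recovered = recovered)
}
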