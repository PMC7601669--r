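# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Trapezoidal integral of y sampled at uniform spacing dx.
trapz_uniform <- function(y, dx) {
  n <- length(y)
  if (n < 2L) return(0)
  dx * (sum(y) - (y[1L] + y[n]) / 2)
}

# Short polynomial fingerprint of an R object, for run manifests and trace
# headers. Not cryptographic; only needs to flag config changes.
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 17
  for (v in utf8ToInt(s)) h <- (h * 31 + v) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# Least-squares slope of y against uniformly spaced time (spacing dt seconds).
ls_slope <- function(y, dt) {
  n <- length(y)
  t <- (seq_len(n) - 1) * dt
  tc <- t - mean(t)
  sum(tc * (y - mean(y))) / sum(tc * tc)
}

stop_domain <- function(...) stop(..., call. = FALSE)
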