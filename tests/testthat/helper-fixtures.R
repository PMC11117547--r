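# Shared fixtures, memoized so expensive objects are built once per run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

# Short synthetic recording for unit tests (8 s keeps filters/windows honest
# without the cost of a full trial).
short_recording <- function(seed = 1, ...) {
  memo(paste0("rec", seed, paste(c(...), collapse = "_")), {
    generate_recording(sim_config(duration = 8, seed = seed, ...))
  })
}

# Full-length preprocessed trial used by the experiment tests.
full_recording <- function(seed = 1) {
  memo(paste0("full", seed), {
    trim_edges(denoise_recording(generate_recording(sim_config(seed = seed))))
  })
}

# Independent direct-summation cross-correlation oracle (O(N * L); kept
# separate from the package's own implementations on purpose).
oracle_xcorr <- function(x, y, lags) {
  n <- length(x); m <- length(y)
  vapply(lags, function(tau) {
    i <- max(1, 1 - tau):min(n, m - tau)
    if (length(i) == 0) return(0)
    sum(x[i] * y[i + tau])
  }, numeric(1))
}

# Tiny deterministic feature table for model/pipeline tests: three latent
# envelope-like predictors plus junk, with a known linear target.
toy_table <- function(n = 120, seed = 9, noise = 0) {
  set.seed(seed)
  X <- cbind(
    a = sin(seq(0, 6 * pi, length.out = n)) + rnorm(n, sd = 0.05),
    b = cos(seq(0, 4 * pi, length.out = n)) + rnorm(n, sd = 0.05),
    c = seq(-1, 1, length.out = n) + rnorm(n, sd = 0.05),
    junk = rnorm(n)
  )
  y <- 2 + 0.8 * X[, "a"] - 0.5 * X[, "b"] + 0.3 * X[, "c"] +
    rnorm(n, sd = noise)
  list(X = X, y = y)
}
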