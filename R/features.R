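#' Sliding-window specification
#'
#' @param length window length in samples (default 250, i.e. 250 ms at
#'   1000 Hz).
#' @param hop hop between consecutive window starts in samples (default 50,
#'   i.e. a new estimate every 50 ms); `1 <= hop <= length`.
#' @param fs sampling rate in Hz.
#' @return an object of class `window_spec`.
#' @export
window_spec <- function(length = 250, hop = 50, fs = 1000) {
  length <- as.integer(length); hop <- as.integer(hop)
  if (hop < 1 || hop > length) stop("require 1 <= hop <= length", call. = FALSE)
  if (fs <= 0) stop("fs must be positive", call. = FALSE)
  structure(list(length = length, hop = hop, fs = fs), class = "window_spec")
}

#' Number of sliding windows
#'
#' `floor((n - length) / hop) + 1` for a signal of `n` samples.
#'
#' @param n signal length in samples.
#' @param spec a [window_spec()].
#' @return integer window count.
#' @export
n_windows <- function(n, spec) {
  stopifnot(inherits(spec, "window_spec"))
  if (n < spec$length) stop("signal shorter than one window", call. = FALSE)
  as.integer((n - spec$length) %/% spec$hop + 1L)
}

#' Slice a signal into sliding windows
#'
#' @param x numeric sample vector, at least one window long.
#' @param spec a [window_spec()].
#' @return a `n_windows x length` matrix, one window per row, with the
#'   0-based window start indices in `attr(, "starts")`.
#' @export
sliding_windows <- function(x, spec) {
  nw <- n_windows(length(x), spec)
  starts <- (seq_len(nw) - 1L) * spec$hop
  idx <- outer(starts, seq_len(spec$length), "+")
  out <- matrix(x[idx], nrow = nw)
  attr(out, "starts") <- starts
  out
}

#' Names of the default 25-feature bank, in extraction order
#'
#' Eight time-domain features (mean absolute value, root mean square,
#' population variance and SD, waveform length, zero crossings, slope-sign
#' changes, integrated absolute value), seven frequency-domain features from
#' a linearly detrended periodogram (mean/median/peak frequency, total and
#' mean power, spectral-moment ratio M2/M1, frequency SD), five
#' time-frequency features (relative energies of the four db4 detail levels
#' and the wavelet entropy over all five subbands) and five nonlinear
#' features (sample entropy and approximate entropy with m = 2,
#' r = 0.2 SD, Higuchi fractal dimension with kmax = 8, Lempel-Ziv
#' complexity after median binarization, detrended fluctuation exponent).
#'
#' @return character vector of length 25.
#' @export
feature_names <- function() {
  c("mav", "rms", "var", "sd", "wl", "zc", "ssc", "iav",
    "mnf", "mdf", "pkf", "tp", "mnp", "smr", "fsd",
    "rwe1", "rwe2", "rwe3", "rwe4", "went",
    "sampen", "apen", "hfd", "lzc", "dfa")
}

#' Extract the 25-feature bank from one window
#'
#' See [feature_names()] for the bank definition and order. Deterministic;
#' a constant (zero-variance) window raises a degenerate-window error
#' because the entropy and fractal estimators are undefined there.
#'
#' @param window numeric vector of at least 64 samples.
#' @param fs sampling rate in Hz.
#' @return named numeric vector of length 25.
#' @export
extract_features <- function(window, fs) {
  x <- as.numeric(window)
  n <- length(x)
  if (n < 64) stop("window must have at least 64 samples", call. = FALSE)
  sd_pop <- sqrt(mean((x - mean(x))^2))
  if (sd_pop == 0) {
    stop("degenerate window: constant signal has undefined entropy/fractal features",
         call. = FALSE)
  }

  ## time domain
  mav <- mean(abs(x))
  rms <- sqrt(mean(x^2))
  v <- sd_pop^2
  wl <- sum(abs(diff(x)))
  zc <- sum(x[-1] * x[-n] < 0)
  d <- diff(x)
  ssc <- sum(d[-1] * d[-(n - 1)] < 0)
  iav <- sum(abs(x))

  ## frequency domain (linearly detrended periodogram, DC excluded)
  xd <- detrend_linear(x)
  P_full <- Mod(stats::fft(xd))^2 / n
  nb <- n %/% 2
  f <- (1:nb) * fs / n
  P <- P_full[2:(nb + 1)]
  tp <- sum(P)
  if (tp <= 0) stop("degenerate window: no spectral power", call. = FALSE)
  mnf <- sum(f * P) / tp
  cs <- cumsum(P)
  mdf <- f[which(cs >= tp / 2)[1]]
  pkf <- f[which.max(P)]
  mnp <- tp / nb
  smr <- sum(f^2 * P) / sum(f * P)
  fsd <- sqrt(sum((f - mnf)^2 * P) / tp)

  ## time-frequency: db4 wavelet subband energies, 4 levels
  we <- dwt_energies(x, levels = 4)
  rel <- we / sum(we)
  went <- -sum(ifelse(rel > 0, rel * log(rel), 0))
  rwe <- rel[1:4]

  ## nonlinear
  se <- sample_entropy_fast(x, m = 2, r = 0.2 * sd_pop)
  ae <- approx_entropy_fast(x, m = 2, r = 0.2 * sd_pop)
  hfd <- higuchi_fd(x, kmax = 8)
  lz <- lz_complexity(x)
  alpha <- dfa_exponent(x)

  out <- c(mav, rms, v, sd_pop, wl, zc, ssc, iav,
           mnf, mdf, pkf, tp, mnp, smr, fsd,
           rwe, went, se, ae, hfd, lz, alpha)
  names(out) <- feature_names()
  if (any(!is.finite(out))) {
    bad <- names(out)[!is.finite(out)]
    stop("non-finite feature value(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  out
}

detrend_linear <- function(x) {
  n <- length(x)
  t <- seq_len(n)
  fit <- stats::lm.fit(cbind(1, t), x)
  fit$residuals
}

# db4 analysis filter pair (8 taps); energies of detail subbands d1..dL and
# the final approximation, via symmetric extension + dyadic downsampling.
.db4_lo <- c(-0.010597401785069032, 0.0328830116668852, 0.030841381835560764,
             -0.18703481171909309, -0.027983769416859854, 0.6308807679298589,
             0.7148465705529157, 0.2303778133088965)
.db4_hi <- c(-0.2303778133088965, 0.7148465705529157, -0.6308807679298589,
             -0.027983769416859854, 0.18703481171909309, 0.030841381835560764,
             -0.0328830116668852, -0.010597401785069032)

dwt_step <- function(x, h) {
  L <- length(h)
  # symmetric (half-point) extension on both sides
  ext <- c(rev(x[seq_len(L - 1)]), x, rev(x[(length(x) - L + 2):length(x)]))
  full <- stats::convolve(ext, rev(h), type = "open")
  # keep the 'valid' part aligned with the input, then downsample by 2
  valid <- full[L:(L + length(x) + L - 2)]
  valid[seq(2, length(valid), by = 2)]
}

dwt_energies <- function(x, levels = 4) {
  a <- x
  en <- numeric(levels + 1)
  for (j in seq_len(levels)) {
    d <- dwt_step(a, .db4_hi)
    a <- dwt_step(a, .db4_lo)
    en[j] <- sum(d^2)
  }
  en[levels + 1] <- sum(a^2)
  en
}

# Chebyshev-distance template match counts for entropy estimators:
# running max over m consecutive entries of the pairwise |x_i - x_j| matrix.
cheb_dist_counts <- function(x, m, r) {
  n <- length(x)
  D <- abs(outer(x, x, "-"))
  M <- D
  for (k in seq_len(m - 1)) {
    nm <- nrow(M) - 1L
    M <- pmax(M[1:nm, 1:nm, drop = FALSE], D[(k + 1):(k + nm), (k + 1):(k + nm), drop = FALSE])
  }
  M <= r
}

#' Sample entropy (vectorized)
#'
#' Richman-Moorman sample entropy: negative log of the conditional
#' probability that sequences matching for `m` points (Chebyshev distance
#' <= r, self-matches excluded) also match for `m + 1` points.
#'
#' @param x numeric vector.
#' @param m embedding dimension (default 2).
#' @param r tolerance (default 0.2 * population SD of `x`).
#' @return sample entropy (non-negative; `Inf` when no m+1 matches exist).
#' @export
sample_entropy_fast <- function(x, m = 2, r = 0.2 * stats::sd(x)) {
  n <- length(x)
  if (n < m + 2) stop("series too short for sample entropy", call. = FALSE)
  # use the first n-m templates for both lengths (standard convention)
  Am <- cheb_dist_counts(x, m, r)
  nt <- n - m
  Am <- Am[1:nt, 1:nt, drop = FALSE]
  Am1 <- cheb_dist_counts(x, m + 1, r)
  B <- sum(Am) - nt          # exclude self-matches
  A <- sum(Am1) - nrow(Am1)
  if (B == 0) return(Inf)
  if (A == 0) return(Inf)
  -log(A / B)
}

#' Approximate entropy (vectorized)
#'
#' Pincus approximate entropy phi(m) - phi(m+1) with self-matches included.
#'
#' @inheritParams sample_entropy_fast
#' @return approximate entropy.
#' @export
approx_entropy_fast <- function(x, m = 2, r = 0.2 * stats::sd(x)) {
  n <- length(x)
  if (n < m + 2) stop("series too short for approximate entropy", call. = FALSE)
  phi <- function(mm) {
    Mm <- cheb_dist_counts(x, mm, r)
    Ci <- rowSums(Mm) / ncol(Mm)
    mean(log(Ci))
  }
  phi(m) - phi(m + 1)
}

#' Higuchi fractal dimension
#'
#' Curve-length scaling estimate over delays k = 1..kmax; the fractal
#' dimension is the slope of log L(k) against log(1/k).
#'
#' @param x numeric vector.
#' @param kmax maximum delay (default 8).
#' @return fractal dimension, typically in [1, 2] for bounded signals.
#' @export
higuchi_fd <- function(x, kmax = 8) {
  n <- length(x)
  Lk <- numeric(kmax)
  for (k in seq_len(kmax)) {
    Lm <- numeric(k)
    for (m in seq_len(k)) {
      idx <- seq(m, n, by = k)
      ni <- length(idx) - 1
      if (ni < 1) { Lm[m] <- NA; next }
      Lm[m] <- sum(abs(diff(x[idx]))) * (n - 1) / (ni * k) / k
    }
    Lk[k] <- mean(Lm, na.rm = TRUE)
  }
  ok <- is.finite(Lk) & Lk > 0   # periodic signals can zero out some scales
  if (sum(ok) < 2) {
    stop("degenerate window: curve length undefined at all scales", call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, log(1 / seq_len(kmax)))[ok, , drop = FALSE],
                       log(Lk[ok]))
  unname(fit$coefficients[2])
}

#' Lempel-Ziv complexity (median binarization, normalized)
#'
#' Binarizes the signal at its median, counts the LZ76 exhaustive parsing
#' production steps `c(n)` and normalizes by `n / log2(n)` (the asymptotic
#' complexity of a random binary sequence), so values near 1 indicate a
#' maximally irregular sequence.
#'
#' @param x numeric vector.
#' @return normalized complexity (> 0).
#' @export
lz_complexity <- function(x) {
  s <- as.integer(x > stats::median(x))
  n <- length(s)
  # LZ76 exhaustive parsing (Kaspar & Schuster scheme)
  c_n <- 1L; l <- 1L; i <- 0L; k <- 1L; k_max <- 1L
  while (l + k <= n) {
    if (s[i + k] == s[l + k]) {
      k <- k + 1L
    } else {
      if (k > k_max) k_max <- k
      i <- i + 1L
      if (i == l) {
        c_n <- c_n + 1L
        l <- l + k_max
        i <- 0L; k <- 1L; k_max <- 1L
      } else {
        k <- 1L
      }
    }
  }
  if (k != 1L || i != 0L) c_n <- c_n + 1L
  c_n * log2(n) / n
}

#' Detrended fluctuation analysis exponent
#'
#' Slope of log fluctuation vs log box size for the integrated,
#' linearly-detrended profile; around 0.5 for white noise, 1.5 for Brownian
#' motion.
#'
#' @param x numeric vector (>= 32 samples).
#' @param scales integer vector of box sizes; default log-spaced between 4
#'   and length(x)/4.
#' @return scaling exponent alpha.
#' @export
dfa_exponent <- function(x, scales = NULL) {
  n <- length(x)
  if (n < 32) stop("series too short for DFA", call. = FALSE)
  if (is.null(scales)) {
    scales <- unique(round(exp(seq(log(4), log(n / 4), length.out = 8))))
  }
  y <- cumsum(x - mean(x))
  Fs <- vapply(scales, function(s) {
    nb <- n %/% s
    res2 <- 0
    t <- seq_len(s)
    X <- cbind(1, t)
    for (b in seq_len(nb)) {
      seg <- y[((b - 1) * s + 1):(b * s)]
      fit <- stats::lm.fit(X, seg)
      res2 <- res2 + sum(fit$residuals^2)
    }
    sqrt(res2 / (nb * s))
  }, numeric(1))
  fit <- stats::lm.fit(cbind(1, log(scales)), log(Fs))
  unname(fit$coefficients[2])
}

#' Per-window force targets
#'
#' Pairs each sliding window with a scalar force target: the mean force over
#' the window (default; the 5 Hz low-passed force is near-constant within a
#' 250 ms window), its last sample, or its centre sample.
#'
#' @param force numeric force vector (same length as the source channel).
#' @param spec a [window_spec()].
#' @param rule `"mean"` (default), `"last"` or `"center"`.
#' @return numeric vector of one target per window.
#' @export
align_targets <- function(force, spec, rule = c("mean", "last", "center")) {
  rule <- match.arg(rule)
  W <- sliding_windows(force, spec)
  switch(rule,
         mean = rowMeans(W),
         last = W[, ncol(W)],
         center = W[, ceiling(ncol(W) / 2)])
}

#' Channels of a feature combination
#'
#' Maps the combination codes F1..F7 to channel subsets of the canonical
#' RF/VL/VM montage: F1 = RF, F2 = VL, F3 = VM, F4 = RF+VL, F5 = RF+VM,
#' F6 = VL+VM, F7 = RF+VL+VM.
#'
#' @param combo one of `"F1"`..`"F7"`.
#' @return character vector of channel labels.
#' @export
feature_combination <- function(combo) {
  map <- list(F1 = "RF", F2 = "VL", F3 = "VM",
              F4 = c("RF", "VL"), F5 = c("RF", "VM"),
              F6 = c("VL", "VM"), F7 = c("RF", "VL", "VM"))
  if (!combo %in% names(map)) {
    stop("unknown feature combination: ", combo, call. = FALSE)
  }
  map[[combo]]
}

#' Build the windowed feature table of a recording
#'
#' Slides the window over each selected channel, extracts the 25-feature
#' bank per window and channel, and aligns a force target with every window.
#' Feature columns are named `<channel>:<feature>` and grouped by channel.
#'
#' @param rec an `mmg_recording`.
#' @param channels character vector of channel labels, or a combination code
#'   `"F1"`..`"F7"`; `NULL` uses all channels.
#' @param spec a [window_spec()].
#' @param target_rule passed to [align_targets()].
#' @return an object of class `feature_table`: list with `X`
#'   (`n_windows x (25 * n_channels)` matrix), `target`, `starts`, `spec`,
#'   `channels`.
#' @export
build_feature_table <- function(rec, channels = NULL, spec = window_spec(fs = rec$fs),
                                target_rule = "mean") {
  stopifnot(inherits(rec, "mmg_recording"))
  if (is.null(channels)) channels <- names(rec$channels)
  if (length(channels) == 1 && grepl("^F[1-7]$", channels)) {
    channels <- feature_combination(channels)
  }
  unknown <- setdiff(channels, names(rec$channels))
  if (length(unknown)) {
    stop("unknown channel label(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  blocks <- lapply(channels, function(ch) {
    W <- sliding_windows(rec$channels[[ch]], spec)
    F <- t(apply(W, 1, extract_features, fs = spec$fs))
    colnames(F) <- paste(ch, feature_names(), sep = ":")
    F
  })
  X <- do.call(cbind, blocks)
  if (any(!is.finite(X))) stop("non-finite entries in feature table", call. = FALSE)
  target <- align_targets(rec$force, spec, rule = target_rule)
  starts <- attr(sliding_windows(rec$force, spec), "starts")
  structure(list(X = X, target = target, starts = starts, spec = spec,
                 channels = channels, target_rule = target_rule),
            class = "feature_table")
}

#' Restrict a feature table to a channel subset
#'
#' Column-slices an existing table (no recomputation), e.g. to evaluate the
#' combinations F1..F7 from one full-montage table.
#'
#' @param table a `feature_table`.
#' @param channels channel labels or a combination code `"F1"`..`"F7"`.
#' @return a `feature_table` containing only the requested channels' columns.
#' @export
subset_channels <- function(table, channels) {
  stopifnot(inherits(table, "feature_table"))
  if (length(channels) == 1 && grepl("^F[1-7]$", channels)) {
    channels <- feature_combination(channels)
  }
  unknown <- setdiff(channels, table$channels)
  if (length(unknown)) {
    stop("channel(s) not in table: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  keep <- sub(":.*$", "", colnames(table$X)) %in% channels
  table$X <- table$X[, keep, drop = FALSE]
  table$channels <- channels
  table
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("Feature table: %d windows x %d features (%s)\n",
              nrow(x$X), ncol(x$X), paste(x$channels, collapse = "+")))
  cat(sprintf("  window %d samples, hop %d @ %g Hz; target = window %s force\n",
              x$spec$length, x$spec$hop, x$spec$fs, x$target_rule))
  invisible(x)
}

#' Write a feature table to CSV (with a JSON sidecar)
#'
#' One row per window: window start index, target, then the feature columns.
#' A `<path>.json` sidecar records the window specification, channel set and
#' target rule so the table is self-describing.
#'
#' @param table a `feature_table`.
#' @param path output file.
#' @param sidecar write the JSON sidecar (default TRUE).
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(table, path, sidecar = TRUE) {
  stopifnot(inherits(table, "feature_table"))
  df <- data.frame(start = table$starts, target = table$target,
                   table$X, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  if (sidecar) {
    meta <- list(window = unclass(table$spec), channels = table$channels,
                 target_rule = table$target_rule,
                 n_windows = nrow(table$X), features = feature_names())
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}
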