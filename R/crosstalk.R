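#' Lag-weighted normalized cross-correlation between two MMG signals
#'
#' Computes, for each retained lag tau,
#' \deqn{R(\tau) = \frac{\sum_n x(n)\, y(n+\tau)}{\sqrt{a\,b}\ \omega(\tau)}}
#' where \eqn{a = \sum_n x(n)^2}, \eqn{b = \sum_n y(n)^2} and
#' \eqn{\omega(\tau) = (\max(N,M) - |\tau|)/\max(N,M)} is the overlap weight
#' that removes the bias of the shrinking summation window
#' (\eqn{\omega(0) = 1}). With the `sqrt` normalization (default) the
#' coefficient of a signal with itself at zero lag is exactly 1; the
#' `printed` compatibility mode divides by \eqn{a\,b} instead.
#'
#' The raw sum is evaluated with an FFT (circular correlation on a
#' zero-padded grid); a direct summation mode is provided as a slow reference.
#'
#' @param x,y numeric sample vectors (each with at least one nonzero sample).
#' @param fs sampling rate in Hz (used to express lags in seconds).
#' @param max_lag maximum absolute lag, in samples, or `"full"` for the whole
#'   range `1-N .. M-1`. Default: `0.5 * fs` samples, capped at half the
#'   shorter signal (the overlap correction is unstable at extreme lags).
#' @param normalization `"sqrt"` (default) or `"printed"`.
#' @param method `"fft"` (default) or `"direct"` (reference summation).
#' @return an object of class `ccc_curve`: list with `lags` (samples), `r`,
#'   `omega`, `a`, `b`, `n`, `m`, `fs`, `normalization`.
#' @seealso [pccc()], [classify_crosstalk()], [pairwise_crosstalk()]
#' @export
cross_correlation <- function(x, y, fs = 1, max_lag = NULL,
                              normalization = c("sqrt", "printed"),
                              method = c("fft", "direct")) {
  normalization <- match.arg(normalization)
  method <- match.arg(method)
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x); m <- length(y)
  if (n == 0 || m == 0) stop("inputs must be non-empty", call. = FALSE)
  a <- sum(x^2); b <- sum(y^2)
  if (a == 0 || b == 0) {
    stop("all-zero input: cross-correlation normalization undefined", call. = FALSE)
  }
  if (is.null(max_lag)) {
    max_lag <- floor(min(0.5 * fs, 0.5 * min(n, m)))
  }
  if (identical(max_lag, "full")) {
    lags <- (1 - n):(m - 1)
  } else {
    max_lag <- as.integer(max_lag)
    if (max_lag < 0) stop("max_lag must be non-negative", call. = FALSE)
    lags <- max(1 - n, -max_lag):min(m - 1, max_lag)
  }

  cc <- if (method == "fft") {
    raw_xcorr_fft(x, y, lags)
  } else {
    raw_xcorr_direct(x, y, lags)
  }

  mx <- max(n, m)
  omega <- (mx - abs(lags)) / mx
  if (any(omega <= 0)) stop("lag range exceeds the overlap weight support", call. = FALSE)
  denom <- if (normalization == "sqrt") sqrt(a * b) else a * b
  r <- cc / (denom * omega)
  if (any(!is.finite(r))) stop("non-finite cross-correlation coefficient", call. = FALSE)

  structure(list(lags = lags, r = r, omega = omega, a = a, b = b,
                 n = n, m = m, fs = fs, normalization = normalization),
            class = "ccc_curve")
}

# sum_n x(n) y(n+tau) for each requested lag, via circular FFT correlation
# on a grid of length >= N+M-1.
raw_xcorr_fft <- function(x, y, lags) {
  n <- length(x); m <- length(y)
  L <- stats::nextn(n + m - 1, 2)
  fx <- stats::fft(c(x, rep(0, L - n)))
  fy <- stats::fft(c(y, rep(0, L - m)))
  cc <- Re(stats::fft(Conj(fx) * fy, inverse = TRUE)) / L
  # index k (0-based) of cc holds lag tau = k for k < M, tau = k - L for tail
  idx <- ifelse(lags >= 0, lags, L + lags) + 1L
  cc[idx]
}

raw_xcorr_direct <- function(x, y, lags) {
  n <- length(x); m <- length(y)
  vapply(lags, function(tau) {
    ns <- max(0L, -tau):min(n - 1L, m - 1L - tau)
    if (length(ns) == 0) return(0)
    sum(x[ns + 1L] * y[ns + tau + 1L])
  }, numeric(1))
}

#' @export
print.ccc_curve <- function(x, ...) {
  pk <- pccc(x)
  cat(sprintf("Cross-correlation curve: N=%d, M=%d, %d lags (%s normalization)\n",
              x$n, x$m, length(x$lags), x$normalization))
  cat(sprintf("  peak |R| = %.4f at lag %+g s\n", pk$pccc, pk$peak_lag))
  invisible(x)
}

#' Peak cross-correlation coefficient (PCCC)
#'
#' The cross-talk magnitude of a muscle pair: the maximum over retained lags
#' of `min(|R(tau)|, 1)` (accelerometer polarity is arbitrary, so the
#' absolute value is used; values are clipped at 1). Ties are broken in
#' favour of the smallest absolute lag.
#'
#' @param curve a `ccc_curve` from [cross_correlation()].
#' @return list with `pccc` (in [0, 1]) and `peak_lag` in seconds.
#' @export
pccc <- function(curve) {
  stopifnot(inherits(curve, "ccc_curve"))
  v <- pmin(abs(curve$r), 1)
  best <- max(v)
  cand <- which(v == best)
  pick <- cand[which.min(abs(curve$lags[cand]))]
  list(pccc = v[pick], peak_lag = curve$lags[pick] / curve$fs)
}

#' Classify a cross-talk magnitude
#'
#' Standard interpretation bands for the peak cross-correlation coefficient:
#' below 0.30 the pair is treated as essentially uncontaminated (`low`),
#' 0.30--0.70 inclusive as `moderate`, and above 0.70 as `high`.
#'
#' @param pccc numeric in [0, 1].
#' @return one of `"low"`, `"moderate"`, `"high"`.
#' @export
classify_crosstalk <- function(pccc) {
  if (!is.numeric(pccc) || any(pccc < 0 | pccc > 1)) {
    stop("pccc must lie in [0, 1]", call. = FALSE)
  }
  out <- ifelse(pccc < 0.30, "low", ifelse(pccc <= 0.70, "moderate", "high"))
  unname(out)
}

canonical_pairs <- function(labels) {
  if (setequal(labels, c("RF", "VL", "VM"))) {
    data.frame(pair = c("MP1", "MP2", "MP3"),
               ch1 = c("RF", "RF", "VL"),
               ch2 = c("VL", "VM", "VM"),
               stringsAsFactors = FALSE)
  } else {
    cmb <- utils::combn(sort(labels), 2)
    data.frame(pair = paste(cmb[1, ], cmb[2, ], sep = "-"),
               ch1 = cmb[1, ], ch2 = cmb[2, ], stringsAsFactors = FALSE)
  }
}

#' Pairwise cross-talk report for a recording
#'
#' Extracts an analysis segment (2 s centred in the recording by default)
#' from every MMG channel and computes the PCCC, peak lag and cross-talk
#' class for each unordered channel pair. For the canonical RF/VL/VM montage
#' the pairs are reported in the standard order MP1 = RF-VL, MP2 = RF-VM,
#' MP3 = VL-VM; other label sets fall back to lexicographic pair names.
#'
#' @param rec an `mmg_recording` with at least two channels.
#' @param segment two-element `c(start, end)` in seconds, or `NULL` for a
#'   2 s window centred in the recording.
#' @param max_lag maximum lag in seconds (default 0.5).
#' @param ... passed on to [cross_correlation()].
#' @return a `data.frame` of class `crosstalk_report` with columns `pair`,
#'   `ch1`, `ch2`, `pccc`, `peak_lag_s`, `class`, `seg_start`, `seg_end`.
#' @export
pairwise_crosstalk <- function(rec, segment = NULL, max_lag = 0.5, ...) {
  stopifnot(inherits(rec, "mmg_recording"))
  labels <- names(rec$channels)
  if (length(labels) < 2) stop("need at least 2 MMG channels", call. = FALSE)
  n <- length(rec$force)
  if (is.null(segment)) {
    mid <- n / (2 * rec$fs)
    segment <- c(mid - 1, mid + 1)
    segment[1] <- max(segment[1], 0)
    segment[2] <- min(segment[2], n / rec$fs)
  }
  i0 <- floor(segment[1] * rec$fs) + 1L
  i1 <- min(n, floor(segment[2] * rec$fs))
  if (i0 < 1 || i1 <= i0) stop("segment must lie within the recording", call. = FALSE)

  pr <- canonical_pairs(labels)
  rows <- lapply(seq_len(nrow(pr)), function(k) {
    x <- rec$channels[[pr$ch1[k]]][i0:i1]
    y <- rec$channels[[pr$ch2[k]]][i0:i1]
    curve <- cross_correlation(x, y, fs = rec$fs,
                               max_lag = floor(max_lag * rec$fs), ...)
    pk <- pccc(curve)
    data.frame(pair = pr$pair[k], ch1 = pr$ch1[k], ch2 = pr$ch2[k],
               pccc = pk$pccc, peak_lag_s = pk$peak_lag,
               class = classify_crosstalk(pk$pccc),
               seg_start = (i0 - 1) / rec$fs, seg_end = i1 / rec$fs,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("crosstalk_report", "data.frame")
  out
}

#' @export
print.crosstalk_report <- function(x, ...) {
  cat("Cross-talk report (PCCC over +/- lag window)\n")
  df <- as.data.frame(x)
  df$pccc <- sprintf("%.4f", df$pccc)
  df$peak_lag_s <- sprintf("%+.3f", df$peak_lag_s)
  print(df[, c("pair", "ch1", "ch2", "pccc", "peak_lag_s", "class")],
        row.names = FALSE)
  invisible(x)
}
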