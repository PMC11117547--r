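#' Grey relational grades of comparison series against a reference
#'
#' Deng's classical grey relational analysis. Every series (the reference and
#' each comparison) is min-max normalized to [0, 1]; the absolute deviation
#' \eqn{\Delta_i(k) = |x_0(k) - x_i(k)|} then enters the grey relational
#' coefficient
#' \deqn{\xi_i(k) = \frac{\Delta_{min} + \rho\,\Delta_{max}}
#'                      {\Delta_i(k) + \rho\,\Delta_{max}}}
#' with the distinguishing coefficient `rho` (default 0.5) and
#' \eqn{\Delta_{min}, \Delta_{max}} pooled over all comparison series in the
#' batch (classical convention; `pooled = FALSE` computes them per series for
#' batch-independent grades). The grade of a series is the mean of its
#' coefficients over k. A comparison identical to the reference has grade 1.
#' In the degenerate case \eqn{\Delta_i(k) + \rho\,\Delta_{max} = 0} (which
#' includes the `rho -> 0` limit at points where
#' \eqn{\Delta_i(k) = \Delta_{min} = 0}) the coefficient is defined as 1.
#'
#' @param reference numeric reference series (length >= 2, non-constant).
#' @param X numeric matrix of comparison series in columns (or a single
#'   vector), same length as `reference`; each column non-constant.
#' @param rho distinguishing coefficient in [0, 1].
#' @param pooled pool Delta_min/Delta_max across the batch (default TRUE).
#' @return named numeric vector of grades in (0, 1].
#' @examples
#' gra_grades(c(0, 0.5, 1), cbind(a = c(1, 0.5, 0)))
#' @export
gra_grades <- function(reference, X, rho = 0.5, pooled = TRUE) {
  if (rho < 0 || rho > 1) stop("rho must lie in [0, 1]", call. = FALSE)
  X <- as.matrix(X)
  if (length(reference) != nrow(X)) stop("length mismatch", call. = FALSE)
  if (length(reference) < 2) stop("series must have length >= 2", call. = FALSE)
  x0 <- minmax_norm(reference, "reference")
  Xn <- X
  for (j in seq_len(ncol(X))) {
    nm <- colnames(X)[j]
    Xn[, j] <- minmax_norm(X[, j], if (is.null(nm)) paste0("series ", j) else nm)
  }
  Delta <- abs(Xn - x0)
  grades <- numeric(ncol(X))
  if (pooled) {
    dmin <- min(Delta); dmax <- max(Delta)
    for (j in seq_len(ncol(X))) {
      grades[j] <- mean(gra_xi(Delta[, j], dmin, dmax, rho))
    }
  } else {
    for (j in seq_len(ncol(X))) {
      dj <- Delta[, j]
      grades[j] <- mean(gra_xi(dj, min(dj), max(dj), rho))
    }
  }
  names(grades) <- colnames(X)
  grades
}

gra_xi <- function(delta, dmin, dmax, rho) {
  num <- dmin + rho * dmax
  den <- delta + rho * dmax
  xi <- ifelse(den == 0, 1, num / den)
  xi
}

minmax_norm <- function(x, name) {
  rng <- range(x)
  if (rng[2] - rng[1] <= 0) {
    stop("degenerate (constant) series: ", name, call. = FALSE)
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Grey relational grade of one comparison series
#'
#' Single-series convenience wrapper around [gra_grades()] (the batch of
#' comparison series then contains only this series, so Delta_min/Delta_max
#' are taken over it alone).
#'
#' @inheritParams gra_grades
#' @param comparison numeric comparison series.
#' @return scalar grade in (0, 1].
#' @export
grey_relational_grade <- function(reference, comparison, rho = 0.5) {
  unname(gra_grades(reference, matrix(comparison, ncol = 1), rho = rho))
}

#' Screen features by grey relational grade against the force target
#'
#' Ranks every feature column of a [build_feature_table()] result by its
#' grey relational grade with respect to the force target, computed on the
#' training rows only, and selects features by rule: the `top_k` highest
#' grades (default 10) or all features with grade at or above a `threshold`.
#'
#' @param table a `feature_table`.
#' @param rho distinguishing coefficient.
#' @param rule `"top_k"` or `"threshold"`.
#' @param top_k number of features kept under the `top_k` rule.
#' @param threshold minimum grade kept under the `threshold` rule.
#' @param train_idx integer indices of the training rows (default: all rows).
#'   Screening must only ever see training rows to avoid leakage.
#' @param pooled passed to [gra_grades()].
#' @return an object of class `gra_result`: list with `grades` (all
#'   features, sorted decreasing), `selected` (character vector of kept
#'   feature names), `mask` (logical in original column order), `rule`,
#'   `rho`.
#' @export
screen_features <- function(table, rho = 0.5, rule = c("top_k", "threshold"),
                            top_k = 10, threshold = 0.6,
                            train_idx = NULL, pooled = TRUE) {
  stopifnot(inherits(table, "feature_table"))
  rule <- match.arg(rule)
  if (ncol(table$X) < 2) stop("need at least 2 features to screen", call. = FALSE)
  if (is.null(train_idx)) train_idx <- seq_len(nrow(table$X))
  Xtr <- table$X[train_idx, , drop = FALSE]
  ytr <- table$target[train_idx]

  ok <- vapply(seq_len(ncol(Xtr)), function(j) {
    diff(range(Xtr[, j])) > 0
  }, logical(1))
  if (!any(ok)) stop("all features are degenerate on the training rows", call. = FALSE)
  grades <- rep(NA_real_, ncol(Xtr))
  names(grades) <- colnames(Xtr)
  grades[ok] <- gra_grades(ytr, Xtr[, ok, drop = FALSE], rho = rho, pooled = pooled)

  if (rule == "top_k") {
    k <- min(top_k, sum(ok))
    sel <- names(sort(grades[ok], decreasing = TRUE))[seq_len(k)]
  } else {
    sel <- names(grades)[!is.na(grades) & grades >= threshold]
    if (length(sel) == 0) {
      sel <- names(which.max(grades))   # keep at least the best feature
    }
  }
  mask <- colnames(table$X) %in% sel
  structure(list(grades = sort(grades, decreasing = TRUE, na.last = TRUE),
                 selected = sel, mask = mask, rule = rule, rho = rho,
                 top_k = top_k, threshold = threshold),
            class = "gra_result")
}

#' @export
print.gra_result <- function(x, ...) {
  cat(sprintf("GRA screening (rho = %g, rule = %s): kept %d of %d features\n",
              x$rho, x$rule, length(x$selected), length(x$grades)))
  top <- utils::head(x$grades, 10)
  cat("  top grades:\n")
  for (nm in names(top)) cat(sprintf("    %-12s %.4f\n", nm, top[nm]))
  invisible(x)
}
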