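#' One LSTM cell step (reference implementation)
#'
#' Applies the six standard LSTM cell equations, in order: forget gate
#' \eqn{f_t = \sigma(W_f [h_{t-1}, x_t] + b_f)}, input gate
#' \eqn{i_t = \sigma(W_i [h_{t-1}, x_t] + b_i)}, cell candidate
#' \eqn{\tilde C_t = \tanh(W_C [h_{t-1}, x_t] + b_C)}, cell state
#' \eqn{C_t = f_t \odot C_{t-1} + i_t \odot \tilde C_t}, output gate
#' \eqn{o_t = \sigma(W_o [h_{t-1}, x_t] + b_o)}, and output
#' \eqn{h_t = o_t \odot \tanh(C_t)}.
#'
#' This pure-R single step is the readable reference against which the
#' compiled full-sequence pass is verified; use [mmg_lstm()] for training.
#'
#' @param params list with per-gate weight matrices `W_f`, `W_i`, `W_C`,
#'   `W_o` (each `hidden x (hidden + input)`) and bias vectors `b_f`, `b_i`,
#'   `b_C`, `b_o` (each length `hidden`).
#' @param h_prev,C_prev previous hidden state and cell state (length
#'   `hidden`).
#' @param x_t input vector at time t.
#' @return list with `h`, `C` and the gate values `f`, `i`, `o` and
#'   candidate `g`.
#' @export
lstm_step <- function(params, h_prev, C_prev, x_t) {
  H <- length(h_prev)
  hx <- c(h_prev, x_t)
  for (nm in c("W_f", "W_i", "W_C", "W_o")) {
    if (!all(dim(params[[nm]]) == c(H, length(hx)))) {
      stop(nm, " must be ", H, " x ", length(hx), call. = FALSE)
    }
  }
  sig <- function(z) 1 / (1 + exp(-z))
  f <- sig(drop(params$W_f %*% hx) + params$b_f)
  i <- sig(drop(params$W_i %*% hx) + params$b_i)
  g <- tanh(drop(params$W_C %*% hx) + params$b_C)
  C <- f * C_prev + i * g
  o <- sig(drop(params$W_o %*% hx) + params$b_o)
  h <- o * tanh(C)
  list(h = h, C = C, f = f, i = i, o = o, g = g)
}

#' Fit a single-layer LSTM force regressor
#'
#' Architecture: input layer, one LSTM hidden layer, a fully connected layer
#' and a scalar regression layer. The network is trained on the full
#' chronological sequence by Adam with root-mean-square error as the loss,
#' with global-norm gradient clipping. Weights are initialized uniformly in
#' +/- 0.08 from `seed`, so training is fully deterministic.
#'
#' @param x numeric feature matrix (`T x D`, rows in chronological order);
#'   standardize features before fitting.
#' @param y numeric target vector of length `T`.
#' @param hidden number of LSTM hidden units (default 100).
#' @param lr initial Adam learning rate (default 0.005).
#' @param epochs maximum training epochs (default 250).
#' @param seed integer seed for weight initialization.
#' @param clip gradient clipping norm (default 1; 0 disables).
#' @return an object of class `mmg_lstm` with components `W`, `b`, `v`, `c`
#'   (weights), `trace` (per-epoch training RMSE), `state` (terminal hidden
#'   and cell state), `fitted`, `config`.
#' @seealso [predict.mmg_lstm()], [lstm_step()]
#' @export
mmg_lstm <- function(x, y, hidden = 100, lr = 0.005, epochs = 250,
                     seed = 1L, clip = 1) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (nrow(x) != length(y)) stop("nrow(x) must equal length(y)", call. = FALSE)
  if (nrow(x) < 2) stop("need at least 2 time steps", call. = FALSE)
  H <- as.integer(hidden); D <- ncol(x)
  if (H < 1) stop("hidden must be >= 1", call. = FALSE)
  set.seed(seed)
  W <- matrix(stats::runif(4 * H * (H + D), -0.08, 0.08), nrow = 4 * H)
  b <- rep(0, 4 * H)
  v <- stats::runif(H, -0.08, 0.08)
  cc <- 0
  fit <- lstm_fit_cpp(x, y, W, b, v, cc, as.integer(epochs), lr, clip)
  if (isTRUE(fit$diverged)) {
    stop("LSTM training diverged (non-finite loss); try a lower learning rate",
         call. = FALSE)
  }
  structure(list(
    W = fit$W, b = drop(fit$b), v = drop(fit$v), c = fit$c,
    trace = drop(fit$trace), final_rmse = fit$final_rmse,
    fitted = drop(fit$fitted),
    state = list(h = drop(fit$h_last), C = drop(fit$C_last)),
    y = y, n = nrow(x), d = D,
    config = list(hidden = H, lr = lr, epochs = as.integer(epochs),
                  seed = as.integer(seed), clip = clip)
  ), class = "mmg_lstm")
}

#' Predict from a fitted LSTM
#'
#' Runs the forward pass over `newdata`. By default the recurrent state is
#' carried over from the end of training, which is the right choice when
#' `newdata` chronologically continues the training sequence (the standard
#' evaluation protocol here: last 10% of the windows). With `reset = TRUE`
#' the state starts from zero.
#'
#' @param object an `mmg_lstm`.
#' @param newdata feature matrix (`T x D`), same columns as training.
#' @param reset start from a zero state instead of the terminal training
#'   state.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.mmg_lstm <- function(object, newdata, reset = FALSE, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$d) stop("feature count mismatch", call. = FALSE)
  H <- object$config$hidden
  st <- if (reset) list(h = rep(0, H), C = rep(0, H)) else object$state
  out <- lstm_forward_cpp(newdata, object$W, object$b, object$v, object$c,
                          st$h, st$C)
  drop(out$yhat)
}

#' @export
print.mmg_lstm <- function(x, ...) {
  cat(sprintf("LSTM force regressor: %d inputs -> %d hidden units -> 1 output\n",
              x$d, x$config$hidden))
  cat(sprintf("  Adam lr %g, %d epochs, clip %g, seed %d; training RMSE %.4g\n",
              x$config$lr, x$config$epochs, x$config$clip, x$config$seed,
              x$final_rmse))
  invisible(x)
}

#' @export
summary.mmg_lstm <- function(object, ...) {
  cat(sprintf("Single-layer LSTM regression (%d parameters)\n",
              length(object$W) + length(object$b) + length(object$v) + 1))
  print(object)
  tr <- object$trace
  cat(sprintf("  loss trace: start %.4g, end %.4g over %d epochs\n",
              tr[1], tr[length(tr)], length(tr)))
  invisible(object)
}

#' @export
coef.mmg_lstm <- function(object, ...) {
  H <- object$config$hidden
  splitW <- function(k) object$W[((k - 1) * H + 1):(k * H), , drop = FALSE]
  list(W_f = splitW(1), W_i = splitW(2), W_C = splitW(3), W_o = splitW(4),
       b_f = object$b[1:H], b_i = object$b[(H + 1):(2 * H)],
       b_C = object$b[(2 * H + 1):(3 * H)], b_o = object$b[(3 * H + 1):(4 * H)],
       v = object$v, c = object$c)
}

#' @export
fitted.mmg_lstm <- function(object, ...) object$fitted

#' @export
residuals.mmg_lstm <- function(object, ...) object$y - object$fitted

#' @export
plot.mmg_lstm <- function(x, ...) {
  graphics::plot(seq_along(x$trace), x$trace, type = "l",
                 xlab = "epoch", ylab = "training RMSE",
                 main = "LSTM training loss", ...)
  invisible(x)
}

#' Fit a one-hidden-layer back-propagation neural network
#'
#' Classic feed-forward network \eqn{y_j = f(\sum_i w_{ij} x_i + b_j)} with a
#' sigmoid hidden layer and linear output, trained by full-batch gradient
#' descent on the mean squared error. Glorot-uniform initialization, seeded.
#'
#' @param x numeric feature matrix (standardized).
#' @param y numeric target.
#' @param hidden hidden layer size (default 10).
#' @param lr learning rate (default 0.2).
#' @param epochs training epochs (default 2000).
#' @param seed integer seed.
#' @return an object of class `mmg_bpnn`.
#' @export
mmg_bpnn <- function(x, y, hidden = 10, lr = 0.2, epochs = 2000, seed = 1L) {
  x <- as.matrix(x); y <- as.numeric(y)
  n <- nrow(x); D <- ncol(x); H <- as.integer(hidden)
  if (n != length(y)) stop("nrow(x) must equal length(y)", call. = FALSE)
  set.seed(seed)
  g1 <- sqrt(6 / (D + H)); g2 <- sqrt(6 / (H + 1))
  W1 <- matrix(stats::runif(D * H, -g1, g1), D, H)
  b1 <- rep(0, H)
  W2 <- matrix(stats::runif(H, -g2, g2), H, 1)
  b2 <- 0
  sig <- function(z) 1 / (1 + exp(-z))
  trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    A <- sig(sweep(x %*% W1, 2, b1, "+"))
    yhat <- drop(A %*% W2) + b2
    e <- yhat - y
    trace[ep] <- mean(e^2)
    if (!is.finite(trace[ep])) {
      stop("BPNN training diverged; try a lower learning rate", call. = FALSE)
    }
    dy <- 2 * e / n
    dW2 <- crossprod(A, dy)
    db2 <- sum(dy)
    dA <- (matrix(dy, ncol = 1) %*% t(W2)) * A * (1 - A)
    dW1 <- crossprod(x, dA)
    db1 <- colSums(dA)
    W1 <- W1 - lr * dW1; b1 <- b1 - lr * db1
    W2 <- W2 - lr * dW2; b2 <- b2 - lr * db2
  }
  A <- sig(sweep(x %*% W1, 2, b1, "+"))
  structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, trace = trace,
                 fitted = drop(A %*% W2) + b2, y = y, d = D,
                 config = list(hidden = H, lr = lr, epochs = epochs,
                               seed = as.integer(seed))),
            class = "mmg_bpnn")
}

#' @export
predict.mmg_bpnn <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$d) stop("feature count mismatch", call. = FALSE)
  sig <- function(z) 1 / (1 + exp(-z))
  A <- sig(sweep(newdata %*% object$W1, 2, object$b1, "+"))
  drop(A %*% object$W2) + object$b2
}

#' @export
print.mmg_bpnn <- function(x, ...) {
  cat(sprintf("BPNN regressor: %d-%d-1, gradient descent (lr %g, %d epochs)\n",
              x$d, x$config$hidden, x$config$lr, x$config$epochs))
  cat(sprintf("  final training MSE %.4g\n", x$trace[length(x$trace)]))
  invisible(x)
}

#' @export
residuals.mmg_bpnn <- function(object, ...) object$y - object$fitted

#' @export
fitted.mmg_bpnn <- function(object, ...) object$fitted

#' Fit an epsilon-SVR force regressor (RBF kernel)
#'
#' Thin wrapper around [e1071::svm()] with the radial basis kernel
#' parameterized by the penalty `C` and kernel width `sigma`
#' (`gamma = 1 / (2 sigma^2)`).
#'
#' @param x numeric feature matrix (standardized).
#' @param y numeric target.
#' @param C penalty (> 0).
#' @param sigma RBF width (> 0).
#' @param epsilon epsilon-tube half width (>= 0).
#' @return an object of class `mmg_svr`.
#' @export
mmg_svr <- function(x, y, C = 10, sigma = 1, epsilon = 0.1) {
  if (C <= 0 || sigma <= 0 || epsilon < 0) {
    stop("require C > 0, sigma > 0, epsilon >= 0", call. = FALSE)
  }
  x <- as.matrix(x)
  fit <- e1071::svm(x, as.numeric(y), type = "eps-regression",
                    kernel = "radial", cost = C, gamma = 1 / (2 * sigma^2),
                    epsilon = epsilon, scale = FALSE)
  structure(list(fit = fit, d = ncol(x), y = as.numeric(y),
                 fitted = drop(stats::predict(fit, x)),
                 config = list(C = C, sigma = sigma, epsilon = epsilon)),
            class = "mmg_svr")
}

#' @export
predict.mmg_svr <- function(object, newdata, ...) {
  drop(stats::predict(object$fit, as.matrix(newdata)))
}

#' @export
print.mmg_svr <- function(x, ...) {
  cat(sprintf("epsilon-SVR (RBF): C = %g, sigma = %g, epsilon = %g, %d SVs\n",
              x$config$C, x$config$sigma, x$config$epsilon, x$fit$tot.nSV))
  invisible(x)
}

#' @export
residuals.mmg_svr <- function(object, ...) object$y - object$fitted

#' Evaluate an estimated force sequence against the observed one
#'
#' Computes the three standard indicators: normalized root-mean-square error
#' \eqn{NRMSE = \sqrt{\frac1N \sum (\hat y_i - y_i)^2} / (y_{max} - y_{min})},
#' mean absolute percentage error
#' \eqn{MAPE = \frac1N \sum |\hat y_i - y_i| / |y_i|} (reported as a
#' fraction, not a percentage), and the Pearson correlation
#' \eqn{R = Cov(\hat y, y) / \sqrt{D(\hat y) D(y)}}.
#'
#' @param y_hat estimated force sequence.
#' @param y observed force sequence (same length, >= 2; must have a nonzero
#'   range, and no zero elements for MAPE).
#' @return an object of class `eval_metrics`: list with `nrmse`, `mape`,
#'   `r`, `n`.
#' @examples
#' evaluate_force(c(1.1, 1.8, 4.4), c(1, 2, 4))
#' @export
evaluate_force <- function(y_hat, y) {
  y_hat <- as.numeric(y_hat); y <- as.numeric(y)
  if (length(y_hat) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(y) < 2) stop("need at least 2 points", call. = FALSE)
  rng <- max(y) - min(y)
  if (rng <= 0) stop("zero target range: NRMSE undefined", call. = FALSE)
  if (any(y == 0)) stop("target contains zero value(s): MAPE undefined", call. = FALSE)
  rmse <- sqrt(mean((y_hat - y)^2))
  nrmse <- rmse / rng
  mape <- mean(abs(y_hat - y) / abs(y))
  r <- stats::cov(y_hat, y) / sqrt(stats::var(y_hat) * stats::var(y))
  structure(list(nrmse = nrmse, mape = mape, r = r, n = length(y)),
            class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf("NRMSE = %.4f, MAPE = %.4f, R = %.4f (n = %d)\n",
              x$nrmse, x$mape, x$r, x$n))
  invisible(x)
}
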