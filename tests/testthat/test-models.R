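zero_params <- function(H, D) {
  Z <- matrix(0, H, H + D)
  list(W_f = Z, W_i = Z, W_C = Z, W_o = Z,
       b_f = rep(0, H), b_i = rep(0, H), b_C = rep(0, H), b_o = rep(0, H))
}

test_that("the LSTM cell equations hold in closed form", {
  # all-zero parameters: sigmoid(0) = 0.5 gates, zero candidate and output
  p <- zero_params(2, 3)
  st <- lstm_step(p, h_prev = rep(0, 2), C_prev = rep(0, 2), x_t = c(1, -2, 3))
  expect_equal(st$f, rep(0.5, 2))
  expect_equal(st$i, rep(0.5, 2))
  expect_equal(st$o, rep(0.5, 2))
  expect_equal(st$g, rep(0, 2))
  expect_equal(st$C, rep(0, 2))
  expect_equal(st$h, rep(0, 2))

  # saturated gates: open input/candidate/output, closed forget
  p <- zero_params(1, 1)
  p$b_i <- 10; p$b_C <- 10; p$b_o <- 10; p$b_f <- -10
  st <- lstm_step(p, 0, 5, 0.3)
  expect_equal(st$C, 1, tolerance = 1e-3)
  expect_equal(st$h, tanh(1), tolerance = 1e-3)

  # memory retention: open forget gate, closed input gate
  p <- zero_params(1, 1)
  p$b_f <- 10; p$b_i <- -10
  st <- lstm_step(p, 0, 0.37, 1.2)
  expect_equal(st$C, 0.37, tolerance = 1e-3)

  expect_error(lstm_step(zero_params(2, 3), rep(0, 2), rep(0, 2), c(1, 2)),
               "W_f")
})

test_that("the compiled forward pass matches the reference cell", {
  set.seed(11)
  H <- 4; D <- 3; TT <- 7
  W <- matrix(runif(4 * H * (H + D), -0.5, 0.5), 4 * H)
  b <- runif(4 * H, -0.2, 0.2)
  v <- runif(H); cc <- 0.1
  X <- matrix(rnorm(TT * D), TT)
  p <- list(W_f = W[1:H, ], W_i = W[(H + 1):(2 * H), ],
            W_C = W[(2 * H + 1):(3 * H), ], W_o = W[(3 * H + 1):(4 * H), ],
            b_f = b[1:H], b_i = b[(H + 1):(2 * H)],
            b_C = b[(2 * H + 1):(3 * H)], b_o = b[(3 * H + 1):(4 * H)])
  h <- rep(0, H); C <- rep(0, H); yref <- numeric(TT)
  for (t in seq_len(TT)) {
    st <- lstm_step(p, h, C, X[t, ])
    h <- st$h; C <- st$C
    yref[t] <- sum(v * h) + cc
  }
  fw <- mmgforce:::lstm_forward_cpp(X, W, b, v, cc, rep(0, H), rep(0, H))
  expect_equal(drop(fw$yhat), yref, tolerance = 1e-12)
  expect_equal(drop(fw$h_last), h, tolerance = 1e-12)
})

test_that("analytic gradients agree with finite differences", {
  set.seed(12)
  H <- 3; D <- 2; TT <- 6
  W <- matrix(runif(4 * H * (H + D), -0.4, 0.4), 4 * H)
  b <- runif(4 * H, -0.1, 0.1); v <- runif(H); cc <- 0.05
  X <- matrix(rnorm(TT * D), TT); y <- rnorm(TT)
  g <- mmgforce:::lstm_loss_grad_cpp(X, y, W, b, v, cc, rep(0, H), rep(0, H))
  eps <- 1e-6
  loss_at <- function(Wp, bp, vp, cp) {
    mmgforce:::lstm_loss_grad_cpp(X, y, Wp, bp, vp, cp, rep(0, H), rep(0, H))$loss
  }
  idx <- cbind(c(1, 5, 9), c(2, 3, 1))
  for (r in seq_len(nrow(idx))) {
    Wp <- W; Wp[idx[r, 1], idx[r, 2]] <- W[idx[r, 1], idx[r, 2]] + eps
    Wm <- W; Wm[idx[r, 1], idx[r, 2]] <- W[idx[r, 1], idx[r, 2]] - eps
    num <- (loss_at(Wp, b, v, cc) - loss_at(Wm, b, v, cc)) / (2 * eps)
    expect_equal(num, g$dW[idx[r, 1], idx[r, 2]], tolerance = 1e-5)
  }
  bp <- b; bp[4] <- b[4] + eps; bm <- b; bm[4] <- b[4] - eps
  expect_equal((loss_at(W, bp, v, cc) - loss_at(W, bm, v, cc)) / (2 * eps),
               g$db[4], tolerance = 1e-5)
  vp <- v; vp[2] <- v[2] + eps; vm <- v; vm[2] <- v[2] - eps
  expect_equal((loss_at(W, b, vp, cc) - loss_at(W, b, vm, cc)) / (2 * eps),
               g$dv[2], tolerance = 1e-5)
})

test_that("LSTM training is deterministic, learnable and inert at zero rate", {
  toy <- toy_table(n = 200)
  st <- zscore_fit(toy$X)
  X <- zscore_apply(toy$X, st)
  y <- (toy$y - mean(toy$y)) / sd(toy$y)

  m1 <- mmg_lstm(X, y, hidden = 16, epochs = 120, seed = 4)
  m2 <- mmg_lstm(X, y, hidden = 16, epochs = 120, seed = 4)
  expect_identical(m1$W, m2$W)
  expect_identical(m1$trace, m2$trace)

  # noiseless linear target is learnable to a small fraction of its SD
  expect_lt(m1$final_rmse, 0.05 * sd(y))

  # zero learning rate leaves the network untouched
  m0 <- mmg_lstm(X, y, hidden = 8, lr = 0, epochs = 10, seed = 4)
  set.seed(4)
  W0 <- matrix(runif(4 * 8 * (8 + ncol(X)), -0.08, 0.08), 4 * 8)
  expect_equal(m0$W, W0, tolerance = 1e-12)
  expect_equal(m0$final_rmse, m0$trace[1], tolerance = 1e-12)

  # predictions carry state by default; reset gives a different warm-up
  p_carry <- predict(m1, X[1:10, ])
  p_reset <- predict(m1, X[1:10, ], reset = TRUE)
  expect_false(identical(p_carry, p_reset))
  expect_error(predict(m1, X[, 1:2]), "mismatch")
})

test_that("LSTM accessors expose the fitted model", {
  toy <- toy_table(n = 80)
  m <- mmg_lstm(scale(toy$X), scale(toy$y)[, 1], hidden = 6, epochs = 30,
                seed = 1)
  cf <- coef(m)
  expect_identical(dim(cf$W_f), c(6L, 6L + 4L))
  expect_length(cf$v, 6)
  expect_length(fitted(m), 80)
  expect_equal(residuals(m), m$y - fitted(m))
  expect_output(print(m), "LSTM")
  expect_output(summary(m), "parameters")
})

test_that("baseline models fit their sanity cases", {
  # BPNN on the identity map
  set.seed(21)
  x <- matrix(seq(-2, 2, length.out = 150) + rnorm(150, sd = 0.01), ncol = 1)
  y <- drop(x)
  m <- mmg_bpnn(x, y, hidden = 8, epochs = 3000, seed = 2)
  idx <- chrono_split(150, 0.8)
  p <- predict(m, x[idx$test, , drop = FALSE])
  expect_gt(cor(p, y[idx$test]), 0.99)

  # SVR with C -> 0 collapses to a near-constant predictor
  set.seed(22)
  xs <- matrix(rnorm(100), ncol = 1)
  ys <- drop(xs) + rnorm(100, sd = 0.1)
  weak <- mmg_svr(xs, ys, C = 1e-4, sigma = 1, epsilon = 0.01)
  expect_lt(sd(predict(weak, xs)), 0.05 * sd(ys))

  # SVR on a noiseless quadratic with sensible hyper-parameters
  xq <- matrix(seq(-1, 1, length.out = 120), ncol = 1)
  yq <- drop(xq)^2
  good <- mmg_svr(xq, yq, C = 100, sigma = 0.3, epsilon = 0.001)
  expect_gt(cor(predict(good, xq), yq), 0.99)
  expect_error(mmg_svr(xq, yq, C = -1), "C > 0")
})

test_that("evaluation metrics match their definitions", {
  ev <- evaluate_force(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ev$nrmse, 0)
  expect_equal(ev$mape, 0)
  expect_equal(ev$r, 1)

  expect_equal(evaluate_force(c(1.1, 1.8, 4.4), c(1, 2, 4))$mape, 0.1)
  expect_equal(evaluate_force(c(1, 2, 4), c(1, 2, 3))$nrmse, sqrt(1 / 3) / 2)

  # affine transforms of the estimate keep R at 1
  expect_equal(evaluate_force(3 * c(1, 2, 3) + 2, c(1, 2, 3))$r, 1)

  expect_error(evaluate_force(c(1, 2, 3), c(0, 1, 2)), "MAPE")
  expect_error(evaluate_force(c(1, 2, 3), c(2, 2, 2)), "range")
  expect_error(evaluate_force(c(1, 2), c(1, 2, 3)), "length")
})

test_that("metric invariances hold over random pairs", {
  set.seed(30)
  for (rep in 1:20) {
    y <- runif(25, 1, 3)
    yh <- y + rnorm(25, sd = 0.2)
    ev <- evaluate_force(yh, y)
    # common positive rescaling leaves NRMSE and MAPE unchanged
    s <- runif(1, 0.5, 4)
    ev_s <- evaluate_force(s * yh, s * y)
    expect_equal(ev_s$nrmse, ev$nrmse, tolerance = 1e-12)
    expect_equal(ev_s$mape, ev$mape, tolerance = 1e-12)
    # positive affine transform of the estimate preserves R
    ev_a <- evaluate_force(2.5 * yh + 1, y)
    expect_equal(ev_a$r, ev$r, tolerance = 1e-12)
    # R computed with the population-variance convention is identical
    # (the n-1 factors cancel)
    n <- length(y)
    r_pop <- (mean(yh * y) - mean(yh) * mean(y)) /
      sqrt((mean(yh^2) - mean(yh)^2) * (mean(y^2) - mean(y)^2))
    expect_equal(ev$r, r_pop, tolerance = 1e-10)
  }
})
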