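sphere <- function(x) sum(x^2)
box2d <- search_space(c("x1", "x2"), lower = -5, upper = 5)

test_that("search spaces validate and decode positions", {
  expect_error(search_space("a", 1, 1), "lower < upper")
  sp <- lstm_search_space()
  hp <- decode_position(c(137.4, 0.0042), sp)
  expect_identical(hp$hidden, 137L)
  expect_equal(hp$lr, 0.0042)
  # clamping
  hp2 <- decode_position(c(1000, 1), sp)
  expect_identical(hp2$hidden, 400L)
  expect_equal(hp2$lr, 0.01)
  # log-scale decoding for the SVR penalty
  hp3 <- decode_position(c(2, 1.5), svr_search_space())
  expect_equal(hp3$C, 100)
  expect_equal(hp3$sigma, 1.5)
})

test_that("the canonical optimizer honours its contracts", {
  # constant fitness: best equals the constant, positions stay in bounds
  res <- gwo(function(x) 7, box2d, pack_size = 5, iters = 3, seed = 1)
  expect_equal(res$best_fitness, 7)
  expect_true(all(res$pack >= -5 & res$pack <= 5))
  expect_equal(res$evaluations, 5 + 5 * 3)

  # one iteration: trace holds the initial best and one update
  res1 <- gwo(sphere, box2d, pack_size = 6, iters = 1, seed = 2)
  expect_length(res1$trace, 2)
  expect_equal(res1$best_fitness, min(res1$trace))

  # best-so-far is monotone non-increasing
  res2 <- gwo(sphere, box2d, pack_size = 10, iters = 30, seed = 3)
  expect_true(all(diff(res2$trace) <= 0))
  expect_equal(res2$best_fitness, min(res2$trace))

  # leaders are the best of the final pack, in order
  lf <- res2$leader_fitness
  expect_lte(lf[["alpha"]], lf[["beta"]])
  expect_lte(lf[["beta"]], lf[["delta"]])
  expect_true(all(lf[["delta"]] <= res2$pack_fitness + 1e-12))

  expect_error(gwo(sphere, box2d, pack_size = 3), "pack_size")
  expect_error(gwo(sphere, box2d, iters = 0), "iters")
})

test_that("positions stay in bounds under an adversarial fitness", {
  # fitness that rewards leaving the box would expose missing clamps
  pull <- function(x) -sum(abs(x))
  res <- igwo(pull, box2d, pack_size = 6, iters = 15, seed = 4)
  expect_true(all(res$pack >= -5 & res$pack <= 5))
  expect_true(all(abs(res$best) <= 5))
})

test_that("non-finite fitness triggers re-sampling and the search survives", {
  # a third of the box is poisoned
  f <- function(x) if (x[1] > 1.5) NaN else sphere(x)
  res <- gwo(f, box2d, pack_size = 6, iters = 10, seed = 5)
  expect_true(is.finite(res$best_fitness))
  expect_true(res$best[1] <= 1.5)
})

test_that("reproducibility and variant reduction hold exactly", {
  r1 <- gwo(sphere, box2d, pack_size = 8, iters = 12, seed = 7)
  r2 <- gwo(sphere, box2d, pack_size = 8, iters = 12, seed = 7)
  expect_identical(r1$best, r2$best)
  expect_identical(r1$trace, r2$trace)

  off <- igwo(sphere, box2d, pack_size = 8, iters = 12, seed = 7,
              chaotic_init = FALSE, cosine_a = FALSE, greedy = FALSE)
  expect_identical(off$best, r1$best)
  expect_identical(off$trace, r1$trace)
  expect_identical(off$pack, r1$pack)
})

test_that("greedy selection makes every wolf's fitness non-increasing", {
  res <- igwo(sphere, box2d, pack_size = 6, iters = 20, seed = 8)
  per_wolf <- apply(res$fit_history, 2, diff)
  expect_true(all(per_wolf <= 1e-12))
  # without greedy selection wolves do sometimes get worse
  res_ng <- igwo(sphere, box2d, pack_size = 6, iters = 20, seed = 8,
                 greedy = FALSE)
  expect_true(any(apply(res_ng$fit_history, 2, diff) > 0))
})

test_that("LSTM tuning decodes, penalizes failures and respects point spaces", {
  toy <- toy_table(n = 60)
  X <- zscore_apply(toy$X, zscore_fit(toy$X))
  y <- (toy$y - mean(toy$y)) / sd(toy$y)

  # nearly collapsed box: the returned configuration is that point
  pt <- search_space(c("hidden", "lr"), lower = c(8, 0.005),
                     upper = c(8 + 1e-9, 0.005 + 1e-12),
                     integer = c(TRUE, FALSE))
  tuned <- tune_lstm(X, y, space = pt, pack_size = 4, iters = 1, seed = 1,
                     fitness_epochs = 3, epochs = 5)
  expect_identical(tuned$config$hidden, 8L)
  expect_equal(tuned$config$lr, 0.005, tolerance = 1e-9)
  expect_s3_class(tuned$model, "mmg_lstm")
  expect_equal(tuned$result$best_fitness, min(tuned$result$trace))

  # a fitness that never returns a finite value is penalized, not fatal
  bad <- gwo(function(x) NaN, box2d, pack_size = 4, iters = 1, seed = 1)
  expect_identical(bad$best_fitness, Inf)
})

test_that("SVR tuning recovers a noiseless quadratic", {
  x <- matrix(seq(-1, 1, length.out = 80), ncol = 1)
  y <- drop(x)^2
  tuned <- tune_svr(x, y, pack_size = 5, iters = 8, seed = 2)
  expect_gt(cor(predict(tuned$model, x), y), 0.99)
  expect_gt(tuned$config$C, 0)
  expect_gt(tuned$config$sigma, 0)
})
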